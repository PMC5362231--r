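# Internal numerical helpers shared across modules.

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# Derive a reproducible child seed from a master seed and an integer offset.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 69621 + as.numeric(offset) * 7919) %% 2147483629)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (weight exp(-x^2)).
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ]^2 * sqrt(pi))[ord])
}

# E[f(mu + s*Z)] with Z ~ N(0,1), via Gauss-Hermite quadrature.
gh_normal_expectation <- function(f, mu = 0, s = 1, n_nodes = 60) {
  gh <- gauss_hermite(n_nodes)
  sum(gh$weights / sqrt(pi) * f(mu + s * sqrt(2) * gh$nodes))
}

# Multivariate normal draws via symmetric eigendecomposition; tolerates
# positive semi-definite (including all-zero) covariance matrices.
rmvnorm_eigen <- function(n, mean, sigma) {
  k <- length(mean)
  stopifnot(nrow(sigma) == k, ncol(sigma) == k)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  Z <- matrix(stats::rnorm(n * k), n, k)
  sweep(Z %*% (t(e$vectors) * sqrt(vals)), 2, mean, `+`)
}

# Moore-Penrose pseudo-inverse for (near-)singular Hessians.
pseudo_inverse <- function(A, tol = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  pos <- abs(e$values) > tol * max(abs(e$values), 1)
  inv <- ifelse(pos, 1 / e$values, 0)
  e$vectors %*% (t(e$vectors) * inv)
}

log_step <- function(stage, ...) {
  message(sprintf("[occufast] %s: %s", stage, paste0(..., collapse = "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
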