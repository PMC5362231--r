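# Independent oracles used to validate the likelihood and fitting code.
# These deliberately use brute-force formulations (latent-state
# enumeration, grid search, Monte Carlo) rather than the package's own
# computational paths.

# Latent-state enumeration: Pr(y) = sum_z Pr(y | z) Pr(z).
enum_site_lik <- function(y, psi, p) {
  p <- rep_len(p, length(y))
  obs <- !is.na(y)
  y <- y[obs]; p <- p[obs]
  lik_z1 <- prod(p^y * (1 - p)^(1 - y))
  lik_z0 <- if (all(y == 0)) 1 else 0
  lik_z1 * psi + lik_z0 * (1 - psi)
}

# Site-by-site enumeration NLL with logistic links, matching the model's
# parameterisation but computed naively.
enum_nll <- function(par, data, occ_terms = character(),
                     det_terms = character()) {
  kb <- 1 + length(occ_terms)
  beta <- par[seq_len(kb)]
  alpha <- par[-seq_len(kb)]
  total <- 0
  for (i in seq_len(nrow(data$y))) {
    y <- data$y[i, ]
    if (all(is.na(y))) next
    x <- c(1, if (length(occ_terms)) data$W[i, occ_terms])
    psi <- plogis(sum(x * beta))
    eta_p <- rep(alpha[1], length(y))
    for (k in seq_along(det_terms))
      eta_p <- eta_p + alpha[k + 1] * data$det_covs[[det_terms[k]]][i, ]
    total <- total - log(enum_site_lik(y, psi, plogis(eta_p)))
  }
  total
}

# Exhaustive grid search for the intercept-only MLE of (psi, p) using
# per-site sufficient statistics (d detections out of n visits).
grid_mle <- function(y, step = 0.001) {
  n <- rowSums(!is.na(y))
  d <- rowSums(y == 1, na.rm = TRUE)
  keep <- n > 0
  n <- n[keep]; d <- d[keep]
  psis <- seq(step, 1 - step, by = step)
  ps <- seq(step, 1 - step, by = step)
  best <- c(NA, NA, Inf)
  for (p in ps) {
    condp <- p^d * (1 - p)^(n - d)
    # vectorised over psi: nll(psi) = -sum log(condp*psi + (d==0)*(1-psi))
    az <- d == 0
    nlls <- vapply(psis, function(psi)
      -sum(log(condp * psi + az * (1 - psi))), 0)
    j <- which.min(nlls)
    if (nlls[j] < best[3]) best <- c(psis[j], p, nlls[j])
  }
  list(psi = best[1], p = best[2], nll = best[3])
}

# Simulate an intercept-only detection dataset.
sim_constant_data <- function(S, T, psi, p, seed) {
  set.seed(seed)
  z <- rbinom(S, 1, psi)
  y <- matrix(rbinom(S * T, 1, p), S, T) * z
  occu_data(y)
}

# All 0/1 histories of length T.
all_histories <- function(T) {
  as.matrix(expand.grid(rep(list(0:1), T)))
}
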