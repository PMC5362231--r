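# Zero-inflated single-season occupancy likelihood with logistic links,
# fitted by maximum likelihood. For each site i with detection history
# y_i (0/1 over visits), the contribution is
#   Pr(y_i | z_i = 1) * psi_i + I(y_i == 0) * (1 - psi_i),
# where psi_i is the occupancy probability, p_ij the per-visit detection
# probability, and the indicator term zero-inflates the all-zero history
# (an unoccupied site yields no detections with probability 1).

#' Zero-inflated likelihood of one site's detection history
#'
#' @param y 0/1 detection vector (NAs allowed, treated as unsurveyed).
#' @param psi Occupancy probability for the site.
#' @param p Per-visit detection probabilities (recycled if scalar).
#' @param log Return the log likelihood (`-Inf` when the value is 0).
#' @return The (log) likelihood contribution.
#' @export
site_likelihood <- function(y, psi, p, log = FALSE) {
  stopifnot(psi >= 0, psi <= 1, all(p >= 0 & p <= 1))
  p <- rep_len(p, length(y))
  obs <- !is.na(y)
  y <- y[obs]; p <- p[obs]
  cond <- prod(ifelse(y == 1, p, 1 - p))
  val <- cond * psi + (if (all(y == 0)) 1 - psi else 0)
  if (log) base::log(val) else val
}

.occ_design <- function(data, occ_terms) {
  X <- matrix(1, nrow(data$y), 1, dimnames = list(NULL, "psi_(Intercept)"))
  if (length(occ_terms)) {
    if (is.null(data$W) || !all(occ_terms %in% colnames(data$W)))
      stop(sprintf("occupancy term(s) not in dataset: %s",
                   paste(setdiff(occ_terms, colnames(data$W)), collapse = ", ")))
    X <- cbind(X, data$W[, occ_terms, drop = FALSE])
    colnames(X) <- c("psi_(Intercept)", paste0("psi_", occ_terms))
  }
  X
}

# Shared pre-processing for the likelihood: drops sites with no visits,
# builds designs and masks once.
.nll_context <- function(data, occ_terms, det_terms) {
  stopifnot(inherits(data, "occu_data"))
  if (length(det_terms) && !all(det_terms %in% names(data$det_covs)))
    stop(sprintf("detection term(s) not in dataset: %s",
                 paste(setdiff(det_terms, names(data$det_covs)), collapse = ", ")))
  n_vis <- rowSums(!is.na(data$y))
  use <- n_vis > 0
  y <- data$y[use, , drop = FALSE]
  obs <- !is.na(y)
  y0 <- ifelse(obs, y, 0L)           # NA-safe copy; masked in sums
  Xo <- .occ_design(data, occ_terms)[use, , drop = FALSE]
  dc <- lapply(data$det_covs[det_terms], function(m) {
    m <- m[use, , drop = FALSE]
    if (any(obs & !is.finite(m))) stop("non-finite detection covariate values")
    ifelse(obs, m, 0)
  })
  if (any(!is.finite(Xo))) stop("non-finite occupancy covariate values")
  list(y = y0, obs = obs, allzero = rowSums(y0) == 0L, Xo = Xo, dc = dc,
       use = use, kb = ncol(Xo), ka = 1L + length(det_terms),
       par_names = c(colnames(Xo), "p_(Intercept)",
                     if (length(det_terms)) paste0("p_", det_terms)))
}

.nll_fn <- function(ctx) {
  force(ctx)
  function(par) {
    beta <- par[seq_len(ctx$kb)]
    alpha <- par[ctx$kb + seq_len(ctx$ka)]
    eta_o <- drop(ctx$Xo %*% beta)
    eta_p <- matrix(alpha[1], nrow(ctx$y), ncol(ctx$y))
    for (k in seq_along(ctx$dc))
      eta_p <- eta_p + alpha[k + 1] * ctx$dc[[k]]
    # log p = log(1-p) + eta, so y*log(p)+(1-y)*log(1-p) = log(1-p)+y*eta
    l1p <- stats::plogis(-eta_p, log.p = TRUE)
    logP <- rowSums((l1p + ctx$y * eta_p) * ctx$obs)
    lpsi <- stats::plogis(eta_o, log.p = TRUE)
    a <- logP + lpsi
    lL <- a
    if (any(ctx$allzero)) {
      bz <- (lpsi - eta_o)[ctx$allzero]   # log(1-psi)
      az <- a[ctx$allzero]
      m <- pmax(az, bz)
      lL[ctx$allzero] <- m + log(exp(az - m) + exp(bz - m))
    }
    -sum(lL)
  }
}

.nll_gr <- function(ctx) {
  force(ctx)
  function(par) {
    beta <- par[seq_len(ctx$kb)]
    alpha <- par[ctx$kb + seq_len(ctx$ka)]
    eta_o <- drop(ctx$Xo %*% beta)
    psi <- stats::plogis(eta_o)
    eta_p <- matrix(alpha[1], nrow(ctx$y), ncol(ctx$y))
    for (k in seq_along(ctx$dc))
      eta_p <- eta_p + alpha[k + 1] * ctx$dc[[k]]
    l1p <- stats::plogis(-eta_p, log.p = TRUE)
    p <- 1 - exp(l1p)
    logP <- rowSums((l1p + ctx$y * eta_p) * ctx$obs)
    P <- exp(logP)
    L <- P * psi + ctx$allzero * (1 - psi)
    # d logL / d eta_psi and the common detection factor psi*P/L
    w_psi <- psi * (1 - psi) * (P - ctx$allzero) / L
    w_det <- psi * P / L
    resid <- (ctx$y - p) * ctx$obs
    g_beta <- -unname(drop(crossprod(ctx$Xo, w_psi)))
    g_alpha <- numeric(ctx$ka)
    rs <- rowSums(resid)
    g_alpha[1] <- -sum(w_det * rs)
    for (k in seq_along(ctx$dc))
      g_alpha[k + 1] <- -sum(w_det * rowSums(resid * ctx$dc[[k]]))
    c(g_beta, g_alpha)
  }
}

#' Negative log-likelihood of the covariate occupancy model
#'
#' Joint parameter vector: occupancy coefficients (intercept first, then
#' one per `occ_terms` column), followed by detection coefficients
#' (intercept, then one per `det_terms` covariate), all on the logit
#' scale. Sites without visits are excluded; computation is in log space
#' throughout.
#'
#' @param par Numeric parameter vector.
#' @param data An [occu_data()] object.
#' @param occ_terms Occupancy covariate names (columns of `data$W`).
#' @param det_terms Detection covariate names (entries of
#'   `data$det_covs`).
#' @return The negative log-likelihood.
#' @export
occu_nll <- function(par, data, occ_terms = character(),
                     det_terms = character()) {
  ctx <- .nll_context(data, occ_terms, det_terms)
  stopifnot(length(par) == ctx$kb + ctx$ka)
  .nll_fn(ctx)(par)
}

#' Fit the covariate occupancy model by maximum likelihood
#'
#' Quasi-Newton (BFGS) minimisation of the zero-inflated negative
#' log-likelihood with an analytic gradient, from `n_starts` dispersed
#' starting points: first a moment-based start (naive occupancy and
#' detection rates), then all zeros, then seeded draws (intercepts from
#' \{-2, 0, 2\}, slopes from N(0, 0.5)). If every start
#' fails to converge the number of starts is escalated (doubled, twice)
#' before giving up. The covariance matrix is the inverse of the
#' numerically differentiated Hessian at the optimum, falling back to a
#' pseudo-inverse (flagged `vcov_degenerate`) when singular.
#'
#' @param data An [occu_data()] object with at least one detection.
#' @param occ_terms Occupancy covariate names (default: all columns of
#'   `data$W`).
#' @param det_terms Detection covariate names (default: none, i.e.
#'   constant detection).
#' @param n_starts Number of starting points (default 5).
#' @param seed Seed for start dispersion.
#' @param control Passed to [stats::optim()] (defaults: `reltol 1e-10`,
#'   `maxit 500`).
#' @return An object of class `occu_fit` with elements `estimates`,
#'   `beta`, `alpha`, `vcov`, `loglik`, `aic`, `converged`, `n_sites`,
#'   `flags`, `occ_terms`, `det_terms`, `data`.
#' @export
fit_occu <- function(data, occ_terms = colnames(data$W),
                     det_terms = character(), n_starts = 5, seed = 1,
                     control = list()) {
  occ_terms <- occ_terms %||% character()
  ctx <- .nll_context(data, occ_terms, det_terms)
  if (!any(ctx$y[ctx$obs] == 1L))
    stop("no detections of the target: year cannot be fitted")
  fn <- .nll_fn(ctx); gr <- .nll_gr(ctx)
  npar <- ctx$kb + ctx$ka
  control <- utils::modifyList(list(reltol = 1e-10, maxit = 500), control)

  # Moment-based first start: naive detection rate among detected sites,
  # and the detected-site fraction corrected for imperfect detection.
  # Starting at zeros (psi = p = 0.5) can stall in a flat region of the
  # zero-inflated likelihood when true p is small.
  moment_start <- function() {
    nv <- rowSums(ctx$obs); det <- rowSums(ctx$y)
    hit <- det > 0
    p0 <- min(max(sum(det[hit]) / max(sum(nv[hit]), 1), 0.02), 0.98)
    psi0 <- mean(hit) / (1 - (1 - p0)^mean(nv))
    st <- numeric(npar)
    st[1] <- logit(min(max(psi0, 0.05), 0.95))
    st[ctx$kb + 1] <- logit(p0)
    st
  }

  run_starts <- function(n, seed) {
    set.seed(seed)
    best <- NULL
    for (s in seq_len(n)) {
      start <- if (s == 1L) moment_start()
      else if (s == 2L) numeric(npar)
      else {
        st <- stats::rnorm(npar, 0, 0.5)
        st[1] <- sample(c(-2, 0, 2), 1)          # occupancy intercept
        st[ctx$kb + 1] <- sample(c(-2, 0, 2), 1) # detection intercept
        st
      }
      opt <- tryCatch(
        stats::optim(start, fn, gr, method = "BFGS", control = control),
        error = function(e) NULL)
      if (is.null(opt) || !all(is.finite(opt$par))) next
      opt$ok <- opt$convergence == 0L
      if (is.null(best) || (opt$ok && !best$ok) ||
          (opt$ok == best$ok && opt$value < best$value - 1e-9))
        best <- opt
    }
    best
  }

  best <- run_starts(n_starts, seed)
  tries <- 0L
  while ((is.null(best) || !best$ok) && tries < 2L) {
    tries <- tries + 1L
    n_starts <- n_starts * 2L
    cand <- run_starts(n_starts, derive_seed(seed, tries))
    if (!is.null(cand) && (is.null(best) || cand$ok ||
                           cand$value < best$value - 1e-9))
      if (is.null(best) || cand$ok || !best$ok) best <- cand
  }
  if (is.null(best)) stop("all optimisation starts failed")

  H <- tryCatch(stats::optimHess(best$par, fn, gr), error = function(e) NULL)
  vcov_degenerate <- FALSE
  V <- NULL
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && any(!is.finite(V))) V <- NULL
    if (!is.null(V) && any(diag(V) < 0)) V <- NULL
  }
  if (is.null(V)) {
    V <- if (is.null(H)) matrix(NA_real_, npar, npar) else pseudo_inverse(H)
    vcov_degenerate <- TRUE
    warning("singular or unavailable Hessian: vcov from pseudo-inverse")
  }
  dimnames(V) <- list(ctx$par_names, ctx$par_names)
  est <- stats::setNames(best$par, ctx$par_names)
  loglik <- -best$value

  structure(list(
    estimates = est,
    beta = est[seq_len(ctx$kb)], alpha = est[ctx$kb + seq_len(ctx$ka)],
    vcov = V, loglik = loglik, aic = 2 * npar - 2 * loglik,
    converged = isTRUE(best$ok), n_sites = nrow(ctx$y),
    n_detections = sum(ctx$y), n_params = npar,
    occ_terms = occ_terms, det_terms = det_terms,
    flags = list(vcov_degenerate = vcov_degenerate,
                 boundary = any(abs(best$par) > 10)),
    n_starts_used = n_starts, data = data
  ), class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf("Occupancy model fit: %d sites, %d detections, %d parameters\n",
              x$n_sites, x$n_detections, x$n_params))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, converged = %s\n",
              x$loglik, x$aic, x$converged))
  se <- sqrt(pmax(diag(x$vcov), 0))
  print(round(cbind(Estimate = x$estimates, SE = se), 4))
  if (x$flags$vcov_degenerate) cat("  [warning] degenerate vcov\n")
  if (x$flags$boundary) cat("  [warning] estimate near boundary\n")
  invisible(x)
}

#' Predict occupancy probabilities from a fit
#'
#' @param fit An `occu_fit`.
#' @param W_new Optional covariate matrix for new sites, already on the
#'   fit's standardised scale (default: the fitted dataset's sites).
#' @return Vector of occupancy probabilities, with the linear predictors
#'   in attribute `"linpred"`.
#' @export
predict_psi <- function(fit, W_new = NULL) {
  X <- .psi_design(fit, W_new)
  eta <- drop(X %*% fit$beta)
  structure(inv_logit(eta), linpred = eta)
}

.psi_design <- function(fit, W_new) {
  if (is.null(W_new)) return(.occ_design(fit$data, fit$occ_terms))
  W_new <- as.matrix(W_new)
  X <- matrix(1, nrow(W_new), 1)
  if (length(fit$occ_terms)) {
    if (!all(fit$occ_terms %in% colnames(W_new)))
      stop(sprintf("missing covariate column(s): %s",
                   paste(setdiff(fit$occ_terms, colnames(W_new)), collapse = ", ")))
    X <- cbind(X, W_new[, fit$occ_terms, drop = FALSE])
  }
  X
}

#' Predict detection probabilities from a fit
#'
#' @param fit An `occu_fit`.
#' @param det_covs Optional named list of visit-covariate matrices
#'   (default: the fitted dataset's).
#' @return Matrix of per-visit detection probabilities.
#' @export
predict_p <- function(fit, det_covs = NULL) {
  det_covs <- det_covs %||% fit$data$det_covs
  if (!all(fit$det_terms %in% names(det_covs)))
    stop("missing detection covariate(s)")
  dims <- if (length(fit$det_terms)) dim(det_covs[[fit$det_terms[1]]])
          else dim(fit$data$y)
  eta <- matrix(fit$alpha[1], dims[1], dims[2])
  for (k in seq_along(fit$det_terms))
    eta <- eta + fit$alpha[k + 1] * det_covs[[fit$det_terms[k]]]
  inv_logit(eta)
}

#' Delta-method standard errors for predicted occupancy
#'
#' First-order propagation of coefficient uncertainty to the probability
#' scale: `se(psi_hat) = psi_hat (1 - psi_hat) sqrt(x' Sigma x)` with `x`
#' the occupancy design row and `Sigma` the occupancy block of the
#' coefficient covariance.
#'
#' @param fit An `occu_fit`.
#' @param W_new Optional standardised covariate matrix (default: fitted
#'   sites).
#' @return Vector of standard errors on the probability scale.
#' @export
delta_method_se_psi <- function(fit, W_new = NULL) {
  X <- .psi_design(fit, W_new)
  kb <- length(fit$beta)
  Sigma <- fit$vcov[seq_len(kb), seq_len(kb), drop = FALSE]
  if (fit$flags$vcov_degenerate)
    warning("vcov is degenerate: delta-method SEs are approximate")
  var_eta <- rowSums((X %*% Sigma) * X)
  psi <- inv_logit(drop(X %*% fit$beta))
  psi * (1 - psi) * sqrt(pmax(var_eta, 0))
}

#' Compare fitted models by AIC
#'
#' All fits must be to the identical detection matrix. Returns the fits
#' ranked by AIC with differences to the best.
#'
#' @param fits Named list of `occu_fit` objects.
#' @return `data.frame` with `model`, `k`, `loglik`, `aic`, `delta_aic`,
#'   sorted ascending by AIC.
#' @export
aic_compare <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "occu_fit")))
  y1 <- fits[[1]]$data$y
  for (f in fits[-1])
    if (!identical(dim(f$data$y), dim(y1)) ||
        !isTRUE(all.equal(f$data$y, y1)))
      stop("fits must be to the identical dataset")
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  out <- data.frame(
    model = nm,
    k = vapply(fits, function(f) f$n_params, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aic = vapply(fits, function(f) f$aic, 0))
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}

#' Serialise a fit to JSON
#'
#' Stores estimates, covariance, likelihood, flags, model terms and any
#' standardisation constants; the data are referenced only by summary.
#'
#' @param fit An `occu_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(estimates = as.list(fit$estimates),
              vcov = fit$vcov, par_names = names(fit$estimates),
              loglik = fit$loglik, aic = fit$aic,
              converged = fit$converged, n_sites = fit$n_sites,
              n_detections = fit$n_detections,
              occ_terms = fit$occ_terms, det_terms = fit$det_terms,
              flags = fit$flags, year = fit$data$year,
              std = fit$data$std)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}
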