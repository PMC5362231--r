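# Annual and regional occupancy indices with parametric-bootstrap
# uncertainty, and weighted-regression trends.

#' Occupancy index: mean estimated occupancy over a site set
#'
#' @param psi_hat Vector of site-level occupancy estimates.
#' @return Their arithmetic mean.
#' @export
occupancy_index <- function(psi_hat) {
  if (!length(psi_hat)) stop("empty occupancy vector")
  mean(psi_hat)
}

# B draws of the occupancy-coefficient vector from MVN(theta_hat, vcov).
.bootstrap_beta <- function(fit, B, seed) {
  if (fit$flags$vcov_degenerate)
    warning("degenerate vcov: bootstrap spread may be understated")
  set.seed(seed)
  kb <- length(fit$beta)
  Sigma <- fit$vcov[seq_len(kb), seq_len(kb), drop = FALSE]
  rmvnorm_eigen(B, fit$beta, Sigma)
}

#' Parametric-bootstrap replicates of the occupancy index
#'
#' Draws `B` coefficient vectors from a multivariate Normal centred at
#' the MLE with the estimated covariance, recomputes the site occupancy
#' probabilities and the index for each draw.
#'
#' @param fit An `occu_fit`.
#' @param W_index Standardised covariates of the index site set (default:
#'   every site in the fitted dataset, including unvisited ones).
#' @param B Number of replicates (default 1000).
#' @param seed Seed for the draws.
#' @return Numeric vector of `B` replicate indices.
#' @export
parametric_bootstrap_indices <- function(fit, W_index = NULL, B = 1000,
                                         seed = 1) {
  X <- .psi_design(fit, W_index)
  betas <- .bootstrap_beta(fit, B, seed)
  colMeans(inv_logit(X %*% t(betas)))
}

#' Empirical confidence interval from bootstrap replicates
#'
#' Equal-tailed interval from the empirical quantiles (type-7, linear
#' interpolation of order statistics).
#'
#' @param replicates Bootstrap replicate values.
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(low, high)`.
#' @export
index_confidence_interval <- function(replicates, level = 0.95) {
  stopifnot(length(replicates) >= 2, level > 0, level < 1)
  q <- stats::quantile(replicates, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Annual occupancy index with bootstrap confidence interval
#'
#' Convenience wrapper combining [occupancy_index()],
#' [parametric_bootstrap_indices()] and [index_confidence_interval()].
#'
#' @inheritParams parametric_bootstrap_indices
#' @param level Confidence level.
#' @param region Optional region label carried through.
#' @return An object of class `occupancy_index`: list with `year`,
#'   `n_sites`, `index`, `ci_low`, `ci_high`, `replicates`, `region`.
#' @export
annual_index <- function(fit, W_index = NULL, B = 1000, seed = 1,
                         level = 0.95, region = NA_character_) {
  psi <- predict_psi(fit, W_index)
  reps <- parametric_bootstrap_indices(fit, W_index, B, seed)
  ci <- index_confidence_interval(reps, level)
  structure(list(year = fit$data$year, n_sites = length(psi),
                 index = occupancy_index(psi), ci_low = ci[["low"]],
                 ci_high = ci[["high"]], replicates = reps,
                 region = region),
            class = "occupancy_index")
}

#' @export
print.occupancy_index <- function(x, ...) {
  cat(sprintf("Occupancy index%s%s: %.4f (95%% CI %.4f-%.4f), %d sites, B=%d\n",
              if (is.na(x$year)) "" else sprintf(" [year %d]", x$year),
              if (is.na(x$region)) "" else sprintf(" [%s]", x$region),
              x$index, x$ci_low, x$ci_high, x$n_sites, length(x$replicates)))
  invisible(x)
}

#' Weighted linear trend in an occupancy index series
#'
#' Fits a weighted linear regression of the index on year, with the
#' inverse standard deviations of each year's bootstrap replicates as
#' weights. The percent change over the window is computed from the
#' fitted values at the window endpoints. Confidence intervals come from
#' refitting the trend to each bootstrap replicate series and taking
#' quantiles of both the slopes and the percent changes.
#'
#' @param years Vector of years.
#' @param index Vector of annual index values (same length).
#' @param replicates B x n_years matrix of bootstrap replicate indices.
#' @param window Length-2 year range over which to estimate the trend
#'   (default: all years).
#' @param level Confidence level.
#' @return An object of class `trend_estimate`: `slope`,
#'   `percent_change`, their CIs, the `window` and the `weights` used.
#' @export
weighted_trend <- function(years, index, replicates,
                           window = range(years), level = 0.95) {
  stopifnot(length(years) == length(index),
            ncol(replicates) == length(years))
  inw <- years >= window[1] & years <= window[2]
  if (sum(inw) < 2) stop("need at least 2 years in the trend window")
  yr <- years[inw]; ix <- index[inw]
  reps <- replicates[, inw, drop = FALSE]
  sds <- apply(reps, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero bootstrap SD for some year(s): weight capped")
    pos <- sds[sds > 0]
    sds[sds == 0] <- if (length(pos)) min(pos) else 1
  }
  w <- 1 / sds

  wls <- function(y) {
    f <- stats::lm.wfit(cbind(1, yr), y, w)
    cf <- f$coefficients
    fit_ends <- cf[1] + cf[2] * window
    c(slope = unname(cf[2]),
      pct = unname((fit_ends[2] - fit_ends[1]) / fit_ends[1] * 100))
  }
  pt <- wls(ix)
  rep_tr <- t(apply(reps, 1, wls))
  a <- c((1 - level) / 2, 1 - (1 - level) / 2)
  structure(list(
    slope = pt[["slope"]], percent_change = pt[["pct"]],
    slope_ci = stats::quantile(rep_tr[, 1], a, names = FALSE),
    percent_change_ci = stats::quantile(rep_tr[, 2], a, names = FALSE),
    window = window, weights = stats::setNames(w, yr), level = level,
    replicate_trends = rep_tr
  ), class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("Occupancy trend %d-%d\n", x$window[1], x$window[2]))
  cat(sprintf("  slope: %.5f / year (%.0f%% CI %.5f to %.5f)\n",
              x$slope, 100 * x$level, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  change: %.2f%% (%.0f%% CI %.2f%% to %.2f%%)\n",
              x$percent_change, 100 * x$level,
              x$percent_change_ci[1], x$percent_change_ci[2]))
  invisible(x)
}

#' Regional occupancy indices from a single national fit
#'
#' Computes per-region indices (and bootstrap CIs) by averaging the
#' fitted site occupancies within each region, reusing one national fit
#' and a single set of shared bootstrap coefficient draws, so that the
#' national index is exactly the site-count-weighted mean of the regional
#' indices, point estimate and replicate by replicate.
#'
#' @param fit An `occu_fit`.
#' @param regions `data.frame` with `site_id` and `region`, one row per
#'   site of the fitted dataset.
#' @param B Number of bootstrap replicates.
#' @param seed Seed.
#' @param level Confidence level.
#' @return `data.frame` (one row per region plus a `"national"` row) with
#'   `region`, `n_sites`, `index`, `ci_low`, `ci_high`; replicate
#'   matrices in attribute `"replicates"`.
#' @export
regional_indices <- function(fit, regions, B = 1000, seed = 1, level = 0.95) {
  stopifnot(is.data.frame(regions),
            all(c("site_id", "region") %in% names(regions)))
  ids <- fit$data$site_ids
  m <- match(ids, regions$site_id)
  if (any(is.na(m)))
    stop(sprintf("no region label for site(s): %s",
                 paste(utils::head(ids[is.na(m)], 3), collapse = ", ")))
  if (anyDuplicated(regions$site_id))
    stop("duplicate site_id in region table")
  lab <- as.character(regions$region[m])
  X <- .psi_design(fit, NULL)
  psi <- inv_logit(drop(X %*% fit$beta))
  betas <- .bootstrap_beta(fit, B, seed)
  psi_rep <- inv_logit(X %*% t(betas))   # sites x B

  groups <- c(split(seq_along(lab), lab), list(national = seq_along(lab)))
  rep_mat <- matrix(NA_real_, B, length(groups),
                    dimnames = list(NULL, names(groups)))
  out <- data.frame(region = names(groups),
                    n_sites = lengths(groups),
                    index = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (j in seq_along(groups)) {
    idx <- groups[[j]]
    out$index[j] <- mean(psi[idx])
    rep_mat[, j] <- colMeans(psi_rep[idx, , drop = FALSE])
    ci <- index_confidence_interval(rep_mat[, j], level)
    out$ci_low[j] <- ci[["low"]]; out$ci_high[j] <- ci[["high"]]
  }
  attr(out, "replicates") <- rep_mat
  out
}

#' Write an index series to CSV
#'
#' @param indices List of `occupancy_index` objects.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(indices, path) {
  df <- do.call(rbind, lapply(indices, function(x)
    data.frame(year = x$year, n_sites = x$n_sites, index = x$index,
               ci_low = x$ci_low, ci_high = x$ci_high, region = x$region)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
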