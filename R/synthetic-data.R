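#' Scenario configuration for the occupancy simulation study
#'
#' Describes one cell of the simulation design used to validate the
#' classical (covariate) and Bayesian (random-effect) occupancy models:
#' 1000 sites, 10 years and 10 annual visits by default, with occupancy on
#' the logit scale driven either by a standard-Normal site covariate whose
#' slope ramps evenly from -0.5 to 0.5 across years, or by a Normal site
#' random effect with variance 5. Detection probability is constant within
#' a scenario, and a fixed fraction of sites is unobserved (all visits
#' missing) in each year, redrawn independently per year.
#'
#' Annual intercepts are, by default, calibrated so that the population
#' mean occupancy probability ramps evenly between
#' `mean_occupancy_endpoints` (0.4 to 0.6), making the grand-mean truth
#' exactly 0.5. Set `intercept_scale = "logit"` to instead use raw logit
#' intercepts spaced between the same endpoints (a sensitivity variant;
#' mean occupancy is then not 0.5).
#'
#' @param occupancy_structure `"covariate"` or `"random_effect"`.
#' @param n_sites,n_years,n_visits Design dimensions.
#' @param p_detect Constant per-visit detection probability.
#' @param missing_fraction Fraction of sites with no visits in a year.
#' @param mean_occupancy_endpoints First- and last-year mean occupancy.
#' @param slope_endpoints First- and last-year covariate slopes.
#' @param re_variance Variance of the site random effect (logit scale).
#' @param seed Integer seed governing all randomness for the scenario.
#' @param intercept_scale `"probability"` (calibrated, default) or
#'   `"logit"` (raw intercepts).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(occupancy_structure = c("covariate", "random_effect"),
                            n_sites = 1000L, n_years = 10L, n_visits = 10L,
                            p_detect = 0.15, missing_fraction = 0.5,
                            mean_occupancy_endpoints = c(0.4, 0.6),
                            slope_endpoints = c(-0.5, 0.5),
                            re_variance = 5, seed = 1L,
                            intercept_scale = c("probability", "logit")) {
  occupancy_structure <- match.arg(occupancy_structure)
  intercept_scale <- match.arg(intercept_scale)
  stopifnot(
    n_sites >= 1, n_years >= 1, n_visits >= 1,
    p_detect > 0, p_detect <= 1,
    missing_fraction >= 0, missing_fraction < 1,
    all(mean_occupancy_endpoints > 0), all(mean_occupancy_endpoints < 1),
    length(mean_occupancy_endpoints) == 2, length(slope_endpoints) == 2,
    re_variance >= 0
  )
  structure(list(
    occupancy_structure = occupancy_structure,
    n_sites = as.integer(n_sites), n_years = as.integer(n_years),
    n_visits = as.integer(n_visits),
    p_detect = p_detect, missing_fraction = missing_fraction,
    mean_occupancy_endpoints = mean_occupancy_endpoints,
    slope_endpoints = slope_endpoints, re_variance = re_variance,
    seed = as.integer(seed), intercept_scale = intercept_scale
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Occupancy simulation scenario\n")
  cat(sprintf("  structure: %s, sites: %d, years: %d, visits: %d\n",
              x$occupancy_structure, x$n_sites, x$n_years, x$n_visits))
  cat(sprintf("  p = %.2f, missing fraction = %.2f, seed = %d\n",
              x$p_detect, x$missing_fraction, x$seed))
  invisible(x)
}

#' Calibrate a logit intercept to a target mean occupancy
#'
#' Finds the intercept `b` such that the population mean of
#' `plogis(b + s * Z)`, with `Z` standard Normal, equals `target_mean`.
#' For the covariate structure `s` is the covariate slope; for the
#' random-effect structure it is the random-effect standard deviation.
#' The expectation is evaluated by Gauss-Hermite quadrature and inverted
#' by 1-D root finding.
#'
#' @param target_mean Target mean occupancy probability, in (0, 1).
#' @param slope_or_sd Covariate slope or random-effect sd.
#' @param structure `"covariate"` or `"random_effect"` (equivalent here;
#'   kept for interface clarity).
#' @param n_nodes Number of quadrature nodes.
#' @return The calibrated intercept (logit scale).
#' @export
calibrate_intercept <- function(target_mean, slope_or_sd = 0,
                                structure = c("covariate", "random_effect"),
                                n_nodes = 60) {
  match.arg(structure)
  if (!is.finite(target_mean) || target_mean <= 0 || target_mean >= 1)
    stop("target_mean must lie strictly in (0, 1)")
  s <- abs(slope_or_sd)
  if (s < 1e-12) return(logit(target_mean))
  f <- function(b) gh_normal_expectation(inv_logit, mu = b, s = s,
                                         n_nodes = n_nodes) - target_mean
  stats::uniroot(f, lower = -50, upper = 50, tol = 1e-12)$root
}

#' Simulate one dataset from a simulation-study scenario
#'
#' Draws a site covariate `x_i ~ N(0,1)` and a site random effect
#' `u_i ~ N(0, re_variance)` once (both are site attributes, fixed across
#' years), then per year forms `logit(psi) = b_t + beta_t x_i` (covariate
#' structure) or `b_t + u_i` (random-effect structure), draws latent
#' occupancy `z ~ Bern(psi)` and detections `y ~ Bern(p) * z` for each
#' visit, and blanks out a randomly drawn `missing_fraction` of sites
#' (all visits `NA`), independently per year.
#'
#' @param config A [scenario_config()].
#' @return An object of class `sim_dataset`: list with `histories` (list
#'   of site x visit 0/1/NA matrices, one per year), `z_true`, `psi_true`
#'   (site x year), `mean_psi_true` (per-year population mean occupancy,
#'   the truth used for index error), `covariate`, `u_true`, `intercepts`,
#'   `slopes` and the `config`.
#' @export
simulate_scenario_dataset <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  S <- config$n_sites; TY <- config$n_years; V <- config$n_visits
  x <- stats::rnorm(S)
  u <- stats::rnorm(S, 0, sqrt(config$re_variance))
  slopes <- seq(config$slope_endpoints[1], config$slope_endpoints[2],
                length.out = TY)
  targets <- seq(config$mean_occupancy_endpoints[1],
                 config$mean_occupancy_endpoints[2], length.out = TY)

  b <- numeric(TY)
  for (t in seq_len(TY)) {
    b[t] <- if (config$intercept_scale == "logit") {
      targets[t]
    } else if (config$occupancy_structure == "covariate") {
      tryCatch(calibrate_intercept(targets[t], slopes[t], "covariate"),
               error = function(e) stop(sprintf(
                 "intercept calibration failed for year %d: %s",
                 t, conditionMessage(e))))
    } else {
      tryCatch(calibrate_intercept(targets[t], sqrt(config$re_variance),
                                   "random_effect"),
               error = function(e) stop(sprintf(
                 "intercept calibration failed for year %d: %s",
                 t, conditionMessage(e))))
    }
  }

  psi <- matrix(NA_real_, S, TY)
  z <- matrix(NA_integer_, S, TY)
  histories <- vector("list", TY)
  n_miss <- as.integer(round(config$missing_fraction * S))
  for (t in seq_len(TY)) {
    eta <- if (config$occupancy_structure == "covariate")
      b[t] + slopes[t] * x else b[t] + u
    psi[, t] <- inv_logit(eta)
    z[, t] <- stats::rbinom(S, 1L, psi[, t])
    y <- matrix(stats::rbinom(S * V, 1L, config$p_detect), S, V) * z[, t]
    if (n_miss > 0) y[sample.int(S, n_miss), ] <- NA_integer_
    histories[[t]] <- y
  }
  mean_psi_true <- if (config$intercept_scale == "logit")
    colMeans(psi) else targets

  structure(list(
    histories = histories, z_true = z, psi_true = psi,
    mean_psi_true = mean_psi_true, covariate = x, u_true = u,
    intercepts = b, slopes = slopes, config = config
  ), class = "sim_dataset")
}

#' Configuration for simulating opportunistic multi-species records
#'
#' Emulates the structure of an opportunistic recording-scheme database:
#' several species with seasonal activity windows and differing
#' commonness, sites with uneven visit intensity, and visits that record
#' a species list (list length >= 1). It makes no attempt to mimic real
#' geography or phenology.
#'
#' @param n_sites,n_species,n_years Design dimensions.
#' @param activity_windows Two-column matrix (start week, end week) per
#'   species, weeks within 1-52. Default: staggered windows within the
#'   April-September flight season (weeks 14-39).
#' @param commonness Per-species per-visit recording probability at an
#'   occupied site, in (0, 1). Default: evenly spread between common and
#'   scarce.
#' @param occupancy Per-species probability that a site is occupied
#'   (drawn once, constant across years; the generator's ground truth).
#'   Default: correlated with commonness, from ~0.8 down to ~0.4.
#' @param visit_rate Expected visits per site per year (mean of a
#'   site-level Gamma intensity, giving uneven coverage).
#' @param first_year First calendar year.
#' @param seed Integer seed.
#' @return An object of class `record_sim_config`.
#' @export
record_sim_config <- function(n_sites = 100L, n_species = 8L, n_years = 5L,
                              activity_windows = NULL, commonness = NULL,
                              occupancy = NULL, visit_rate = 6,
                              first_year = 2001L, seed = 1L) {
  n_sites <- as.integer(n_sites); n_species <- as.integer(n_species)
  n_years <- as.integer(n_years)
  stopifnot(n_sites >= 1, n_species >= 1, n_years >= 1, visit_rate > 0)
  if (is.null(activity_windows)) {
    start <- round(seq(14, 30, length.out = n_species))
    end <- pmin(start + round(seq(12, 8, length.out = n_species)), 39)
    activity_windows <- cbind(start, end)
  }
  activity_windows <- matrix(as.integer(activity_windows), ncol = 2)
  stopifnot(nrow(activity_windows) == n_species,
            all(activity_windows >= 1), all(activity_windows <= 52),
            all(activity_windows[, 1] <= activity_windows[, 2]))
  if (is.null(commonness))
    commonness <- inv_logit(seq(1.2, -1.2, length.out = n_species))
  stopifnot(length(commonness) == n_species,
            all(commonness > 0), all(commonness < 1))
  if (is.null(occupancy))
    occupancy <- inv_logit(seq(1.5, -0.5, length.out = n_species))
  stopifnot(length(occupancy) == n_species,
            all(occupancy > 0), all(occupancy <= 1))
  structure(list(
    n_sites = n_sites, n_species = n_species, n_years = n_years,
    activity_windows = activity_windows, commonness = commonness,
    occupancy = occupancy, visit_rate = visit_rate,
    first_year = as.integer(first_year),
    seed = as.integer(seed)
  ), class = "record_sim_config")
}

#' Simulate an opportunistic occurrence-record table
#'
#' Generates one row per (site, date, species) sighting. Each species
#' occupies a random subset of sites (drawn once, constant across
#' years). Visits occur at random dates drawn from weeks in which at
#' least one species is active; each species that is active and occupies
#' the site is recorded independently with its commonness probability,
#' and every visit is guaranteed to record at least one species (a visit
#' only exists because something was recorded). Visits where nothing
#' could be recorded (no active occupant) leave no trace, mimicking
#' presence-only recording.
#'
#' The latent site x species occupancy matrix is attached as attribute
#' `"occupancy"` so downstream estimates can be checked against ground
#' truth.
#'
#' @param config A [record_sim_config()].
#' @return A `data.frame` with columns `site_id`, `date` (`Date`),
#'   `species`, sorted by site, date, species, with attribute
#'   `"occupancy"`.
#' @export
simulate_opportunistic_records <- function(config) {
  stopifnot(inherits(config, "record_sim_config"))
  set.seed(config$seed)
  n_sp <- config$n_species
  win <- config$activity_windows
  active_weeks <- sort(unique(unlist(lapply(seq_len(n_sp), function(s)
    seq(win[s, 1], win[s, 2])))))
  site_ids <- sprintf("S%04d", seq_len(config$n_sites))
  sp_ids <- sprintf("sp%02d", seq_len(n_sp))
  # Latent occupancy: which sites each species occupies (all years).
  occ <- matrix(stats::rbinom(config$n_sites * n_sp, 1L,
                              rep(config$occupancy, each = config$n_sites)),
                config$n_sites, n_sp, dimnames = list(site_ids, sp_ids))
  # Site-level visit intensity: Gamma with mean visit_rate, cv 1/sqrt(2).
  rate_i <- stats::rgamma(config$n_sites, shape = 2,
                          scale = config$visit_rate / 2)

  out <- vector("list", 0L)
  for (yr in config$first_year + seq_len(config$n_years) - 1L) {
    jan1 <- as.Date(sprintf("%d-01-01", yr))
    n_vis <- stats::rpois(config$n_sites, rate_i)
    for (i in which(n_vis > 0)) {
      wk <- sample(active_weeks, n_vis[i], replace = TRUE)
      doy <- pmin((wk - 1L) * 7L + sample.int(7L, n_vis[i], replace = TRUE) - 1L,
                  364L)
      dates <- unique(jan1 + doy)
      for (d in seq_along(dates)) {
        w <- as.integer(ceiling(as.integer(dates[d] - jan1 + 1L) / 7))
        act <- which(win[, 1] <= w & win[, 2] >= w & occ[i, ] == 1L)
        if (!length(act)) next
        hit <- act[stats::runif(length(act)) < config$commonness[act]]
        if (!length(hit))
          hit <- act[sample.int(length(act), 1L,
                                prob = config$commonness[act])]
        out[[length(out) + 1L]] <- data.frame(
          site_id = site_ids[i], date = dates[d], species = sp_ids[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  rec <- if (!length(out)) {
    data.frame(site_id = character(), date = as.Date(character()),
               species = character(), stringsAsFactors = FALSE)
  } else {
    r <- do.call(rbind, out)
    r <- r[order(r$site_id, r$date, r$species), , drop = FALSE]
    rownames(r) <- NULL
    r
  }
  attr(rec, "occupancy") <- occ
  rec
}

#' Write a simulated scenario dataset to a directory of CSV files
#'
#' One `history_year<t>.csv` per year (site x visit 0/1/NA matrix) plus
#' `truth.csv` (site covariate, random effect, per-year psi and z) and
#' `meta.json` describing the scenario.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  TY <- dataset$config$n_years
  for (t in seq_len(TY))
    utils::write.csv(dataset$histories[[t]],
                     file.path(dir, sprintf("history_year%02d.csv", t)),
                     row.names = FALSE)
  truth <- data.frame(site = seq_len(dataset$config$n_sites),
                      covariate = dataset$covariate, u = dataset$u_true)
  for (t in seq_len(TY)) {
    truth[[sprintf("psi_%02d", t)]] <- dataset$psi_true[, t]
    truth[[sprintf("z_%02d", t)]] <- dataset$z_true[, t]
  }
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  meta <- unclass(dataset$config)
  meta$mean_psi_true <- dataset$mean_psi_true
  meta$intercepts <- dataset$intercepts
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
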