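# Preparation of opportunistic occurrence records into detection
# histories: visits are inferred from sightings of any (benchmark)
# species, giving presence/inferred-absence data for a target species.

.rec_year <- function(records) as.integer(format(as.Date(records$date), "%Y"))
.rec_month <- function(records) as.integer(format(as.Date(records$date), "%m"))

# Week convention: ceil(day-of-year / 7), weeks 1-53. Stable across years.
date_to_week <- function(date) {
  doy <- as.integer(format(as.Date(date), "%j"))
  as.integer(ceiling(doy / 7))
}

.check_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("site_id", "date", "species") %in% names(records)))
  records$date <- as.Date(records$date)
  if (any(is.na(records$date))) stop("records contain invalid dates")
  if (any(!nzchar(records$site_id))) stop("records contain empty site_id")
  records
}

#' Keep only sites recorded in at least a minimum number of years
#'
#' A site qualifies if any species was recorded there in at least
#' `min_years` distinct calendar years; all records from other sites are
#' dropped. This removes sites visited too rarely for occupancy
#' inference.
#'
#' @param records Occurrence records (`site_id`, `date`, `species`).
#' @param min_years Minimum number of distinct years with records.
#' @return The filtered record table.
#' @export
filter_sites_by_min_years <- function(records, min_years = 3) {
  stopifnot(min_years >= 1)
  records <- .check_records(records)
  yrs <- .rec_year(records)
  n_years <- tapply(yrs, records$site_id, function(v) length(unique(v)))
  keep <- names(n_years)[n_years >= min_years]
  out <- records[records$site_id %in% keep, , drop = FALSE]
  if (!nrow(out)) warning("no sites satisfy the minimum-years filter")
  log_step("min-years filter", sprintf("%d -> %d records (min_years=%d)",
                                       nrow(records), nrow(out), min_years))
  rownames(out) <- NULL
  out
}

#' Restrict records to the main flight season
#'
#' Retains records whose calendar month lies in `[start_month,
#' end_month]` (default April-September), the within-year window over
#' which site occupancy is assumed closed for adult butterflies.
#'
#' @param records Occurrence records.
#' @param start_month,end_month Month bounds (1-12).
#' @return The filtered record table.
#' @export
restrict_to_flight_season <- function(records, start_month = 4, end_month = 9) {
  stopifnot(start_month >= 1, start_month <= end_month, end_month <= 12)
  records <- .check_records(records)
  m <- .rec_month(records)
  out <- records[m >= start_month & m <= end_month, , drop = FALSE]
  log_step("season filter", sprintf("%d -> %d records (months %d-%d)",
                                    nrow(records), nrow(out),
                                    start_month, end_month))
  rownames(out) <- NULL
  out
}

#' Build visits from records for one year
#'
#' A visit is a unique (site, date) on which at least one species was
#' recorded. Its list length is the number of distinct species recorded
#' (duplicated rows of one species count once), a proxy for recording
#' effort. If `target` is supplied, `target_detected` marks visits on
#' which the target species was recorded.
#'
#' @param records Occurrence records.
#' @param year Calendar year to extract.
#' @param target Optional target species code.
#' @return A `data.frame` with `site_id`, `date`, `week`, `month`,
#'   `list_length` and (if `target` given) `target_detected`.
#' @export
build_visits <- function(records, year, target = NULL) {
  records <- .check_records(records)
  rec <- records[.rec_year(records) == year, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("no records for year %d", year))
  key <- paste(rec$site_id, rec$date, sep = "\r")
  ll <- tapply(rec$species, key, function(s) length(unique(s)))
  first <- !duplicated(key)
  visits <- data.frame(site_id = rec$site_id[first], date = rec$date[first],
                       stringsAsFactors = FALSE)
  visits$week <- date_to_week(visits$date)
  visits$month <- as.integer(format(visits$date, "%m"))
  visits$list_length <- as.integer(ll[key[first]])
  if (!is.null(target)) {
    det_keys <- unique(key[rec$species == target])
    visits$target_detected <- as.integer(key[first] %in% det_keys)
  }
  visits <- visits[order(visits$site_id, visits$date), , drop = FALSE]
  rownames(visits) <- NULL
  visits
}

#' Trim visits to the target species' activity months
#'
#' Non-target sightings outside the first and last month in which the
#' target was observed that year are disregarded, so that inferred
#' non-detections are not created when the target is not in flight.
#' Visits with target detections are never removed.
#'
#' @param visits Visit table from [build_visits()] with
#'   `target_detected`.
#' @param target Target species code (for error messages).
#' @param year Year (for error messages).
#' @return The trimmed visit table.
#' @export
trim_to_target_activity_months <- function(visits, target, year) {
  stopifnot(is.data.frame(visits), "target_detected" %in% names(visits))
  det <- visits$target_detected == 1L
  if (!any(det))
    stop(sprintf("species '%s' has no records in year %s: cannot be fitted",
                 target, year))
  rng <- range(visits$month[det])
  out <- visits[visits$month >= rng[1] & visits$month <= rng[2], , drop = FALSE]
  log_step("activity trim", sprintf("%d -> %d visits (months %d-%d)",
                                    nrow(visits), nrow(out), rng[1], rng[2]))
  rownames(out) <- NULL
  out
}

#' Cap the number of visits per site-year
#'
#' Site-years with more than `max_visits` visits are thinned by removing
#' non-detection visits uniformly at random (seeded) until the cap is
#' met; visits with target detections are always kept. If detections
#' alone exceed the cap, all detections are kept (the cap is exceeded)
#' with a warning.
#'
#' @param visits Visit table with `target_detected`.
#' @param max_visits Cap on visits per site-year.
#' @param seed Optional seed for the random thinning.
#' @return The capped visit table.
#' @export
cap_visits <- function(visits, max_visits = 50, seed = NULL) {
  stopifnot(max_visits >= 1, is.data.frame(visits),
            "target_detected" %in% names(visits))
  if (!is.null(seed)) set.seed(seed)
  yr <- as.integer(format(as.Date(visits$date), "%Y"))
  grp <- paste(visits$site_id, yr, sep = "\r")
  keep <- rep(TRUE, nrow(visits))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) <= max_visits) next
    det <- idx[visits$target_detected[idx] == 1L]
    non <- idx[visits$target_detected[idx] == 0L]
    if (length(det) >= max_visits) {
      warning(sprintf("site-year %s: %d detection visits exceed cap %d; all kept",
                      sub("\r", "/", g), length(det), max_visits))
      keep[non] <- FALSE
    } else {
      drop_n <- length(idx) - max_visits
      keep[sample(non, drop_n)] <- FALSE
    }
  }
  out <- visits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weekly proportion of records that are of the target species
#'
#' For each week of the year, the number of target records divided by the
#' total number of records that week (0 for weeks with no records). Used
#' as a visit-level detection covariate: a proxy for the seasonal
#' variation in the target's population size, normalised for recording
#' effort. `method = "distribution"` instead divides each week's target
#' count by the year's total target count (the share of target records
#' falling in that week).
#'
#' @param records Occurrence records.
#' @param target Target species code.
#' @param year Calendar year.
#' @param method `"share"` (default) or `"distribution"`.
#' @return Numeric vector of length 53 (weeks), values in \[0, 1\].
#' @export
weekly_target_proportion <- function(records, target, year,
                                     method = c("share", "distribution")) {
  method <- match.arg(method)
  records <- .check_records(records)
  rec <- records[.rec_year(records) == year, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("no records for year %d", year))
  wk <- date_to_week(rec$date)
  tot <- tabulate(wk, nbins = 53)
  tgt <- tabulate(wk[rec$species == target], nbins = 53)
  if (method == "share") {
    out <- ifelse(tot > 0, tgt / tot, 0)
  } else {
    out <- if (sum(tgt) > 0) tgt / sum(tgt) else rep(0, 53)
  }
  out
}

#' Standardise covariate columns to zero mean and unit variance
#'
#' Uses the sample-sd convention. The centring/scaling constants are
#' returned so that covariates for new sites (e.g. a prediction grid) can
#' be placed on the same scale.
#'
#' @param W_raw Numeric matrix or data.frame of covariates.
#' @return List with `W` (standardised matrix), `means`, `sds`.
#' @export
standardise_covariates <- function(W_raw) {
  W <- as.matrix(W_raw)
  storage.mode(W) <- "double"
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  means <- colMeans(W)
  sds <- apply(W, 2, stats::sd)
  bad <- which(!is.finite(sds) | sds <= 0)
  if (length(bad))
    stop(sprintf("zero-variance covariate column(s): %s",
                 paste(colnames(W)[bad], collapse = ", ")))
  list(W = sweep(sweep(W, 2, means), 2, sds, `/`), means = means, sds = sds)
}

#' Apply stored standardisation constants to new covariates
#'
#' @param W_raw Covariates for new sites (same columns).
#' @param std A list with `means` and `sds` as returned by
#'   [standardise_covariates()].
#' @return Standardised matrix.
#' @export
apply_standardisation <- function(W_raw, std) {
  W <- as.matrix(W_raw)
  storage.mode(W) <- "double"
  cols <- names(std$means)
  if (!all(cols %in% colnames(W)))
    stop(sprintf("missing covariate column(s): %s",
                 paste(setdiff(cols, colnames(W)), collapse = ", ")))
  W <- W[, cols, drop = FALSE]
  sweep(sweep(W, 2, std$means), 2, std$sds, `/`)
}

#' Detection-history dataset constructor
#'
#' Low-level container for one season of detection data: a site x visit
#' 0/1/NA detection matrix, optional standardised site covariates for
#' occupancy, and visit-level detection covariates (matrices conformable
#' with `y`). Rows that are entirely `NA` (sites with no usable visits)
#' are retained for prediction but excluded from likelihoods.
#'
#' @param y Site x visit matrix of 0/1/NA detections.
#' @param W Optional site covariate matrix (standardised), rows matching
#'   `y`.
#' @param det_covs Named list of site x visit covariate matrices.
#' @param site_ids Site identifiers (default row numbers).
#' @param year Season year (metadata).
#' @param std Optional standardisation constants for `W`.
#' @param meta Optional list of preparation metadata.
#' @return An object of class `occu_data`.
#' @export
occu_data <- function(y, W = NULL, det_covs = list(), site_ids = NULL,
                      year = NA_integer_, std = NULL, meta = list()) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  stopifnot(all(y %in% c(0L, 1L, NA_integer_)))
  if (!is.null(W)) {
    W <- as.matrix(W)
    storage.mode(W) <- "double"
    stopifnot(nrow(W) == nrow(y))
    if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  }
  for (nm in names(det_covs)) {
    det_covs[[nm]] <- as.matrix(det_covs[[nm]])
    stopifnot(all(dim(det_covs[[nm]]) == dim(y)))
  }
  if (is.null(site_ids)) site_ids <- as.character(seq_len(nrow(y)))
  stopifnot(length(site_ids) == nrow(y))
  structure(list(y = y, W = W, det_covs = det_covs,
                 site_ids = as.character(site_ids),
                 year = as.integer(year), std = std, meta = meta),
            class = "occu_data")
}

#' @export
print.occu_data <- function(x, ...) {
  n_vis <- rowSums(!is.na(x$y))
  cat(sprintf("Detection dataset%s: %d sites (%d with visits), max %d visits\n",
              if (is.na(x$year)) "" else sprintf(" [year %d]", x$year),
              nrow(x$y), sum(n_vis > 0), ncol(x$y)))
  cat(sprintf("  detections: %d; occupancy covariates: %s; detection covariates: %s\n",
              sum(x$y == 1L, na.rm = TRUE),
              if (is.null(x$W)) "none" else paste(colnames(x$W), collapse = ", "),
              if (!length(x$det_covs)) "none"
              else paste(names(x$det_covs), collapse = ", ")))
  invisible(x)
}

#' Assemble a detection dataset for one species and year
#'
#' Runs the full preparation pipeline, in this order: flight-season
#' restriction, minimum-years site filter, visit construction, trimming
#' to the target's activity months, and the per-site-year visit cap.
#' Detection covariates are the log list length and the weekly target
#' proportion for each visit's week; occupancy covariates are
#' standardised, with optional squared-then-restandardised quadratic
#' terms (suffix `_sq`). Sites that pass the record filters but have no
#' usable visits in `year` appear as all-`NA` rows, kept for prediction.
#'
#' @param records Occurrence records (all years, all species).
#' @param target Target species code.
#' @param year Season year to assemble.
#' @param site_covariates Optional `data.frame` with `site_id` plus
#'   numeric covariate columns covering every retained site.
#' @param min_years Minimum-years site filter (default 3).
#' @param season Start/end months of the flight season (default 4, 9).
#' @param max_visits Visit cap per site-year (default 50).
#' @param quadratic Character vector of covariate names to also enter
#'   squared.
#' @param list_length_log Model list length on the log scale (default) or
#'   linearly.
#' @param weekly_prop_method Passed to [weekly_target_proportion()].
#' @param seed Seed for the visit-cap thinning.
#' @return An [occu_data()] object.
#' @export
assemble_detection_dataset <- function(records, target, year,
                                       site_covariates = NULL,
                                       min_years = 3, season = c(4, 9),
                                       max_visits = 50,
                                       quadratic = character(),
                                       list_length_log = TRUE,
                                       weekly_prop_method = "share",
                                       seed = NULL) {
  records <- .check_records(records)
  rec <- restrict_to_flight_season(records, season[1], season[2])
  rec <- filter_sites_by_min_years(rec, min_years)
  if (!nrow(rec)) stop("no records remain after filtering")
  site_ids <- sort(unique(rec$site_id))

  visits <- build_visits(rec, year, target)
  visits <- trim_to_target_activity_months(visits, target, year)
  visits <- cap_visits(visits, max_visits, seed)
  wkprop <- weekly_target_proportion(rec, target, year,
                                     method = weekly_prop_method)

  counts <- table(factor(visits$site_id, levels = site_ids))
  Tmax <- max(1L, max(counts))
  S <- length(site_ids)
  y <- matrix(NA_integer_, S, Tmax)
  ll_cov <- matrix(NA_real_, S, Tmax)
  wp_cov <- matrix(NA_real_, S, Tmax)
  split_idx <- split(seq_len(nrow(visits)), visits$site_id)
  for (i in seq_len(S)) {
    idx <- split_idx[[site_ids[i]]]
    if (is.null(idx)) next
    k <- length(idx)
    y[i, seq_len(k)] <- visits$target_detected[idx]
    g <- visits$list_length[idx]
    ll_cov[i, seq_len(k)] <- if (list_length_log) log(g) else g
    wp_cov[i, seq_len(k)] <- wkprop[visits$week[idx]]
  }

  W <- NULL; std <- NULL
  if (!is.null(site_covariates)) {
    stopifnot("site_id" %in% names(site_covariates))
    miss <- setdiff(site_ids, site_covariates$site_id)
    if (length(miss))
      stop(sprintf("site covariates missing for %d site(s), e.g. %s",
                   length(miss), miss[1]))
    sc <- site_covariates[match(site_ids, site_covariates$site_id), ,
                          drop = FALSE]
    W_raw <- as.matrix(sc[, setdiff(names(sc), "site_id"), drop = FALSE])
    s1 <- standardise_covariates(W_raw)
    W <- s1$W
    std <- list(means = s1$means, sds = s1$sds, quadratic = quadratic)
    for (q in quadratic) {
      if (!q %in% colnames(W)) stop(sprintf("unknown quadratic term '%s'", q))
      s2 <- standardise_covariates(matrix(W[, q]^2, ncol = 1,
                                          dimnames = list(NULL, paste0(q, "_sq"))))
      W <- cbind(W, s2$W)
      std$means <- c(std$means, s2$means)
      std$sds <- c(std$sds, s2$sds)
    }
  }

  occu_data(y = y, W = W,
            det_covs = list(log_list_length = ll_cov, week_prop = wp_cov),
            site_ids = site_ids, year = year, std = std,
            meta = list(target = target, min_years = min_years,
                        season = season, max_visits = max_visits,
                        weekly_prop_method = weekly_prop_method,
                        list_length_log = list_length_log,
                        n_visits_used = nrow(visits), seed = seed))
}

#' Write a detection dataset to a directory
#'
#' Plain-text serialisation: `y.csv` (detection matrix), per-covariate
#' CSVs and `meta.json` (filters applied, standardisation constants).
#'
#' @param data An `occu_data` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_detection_dataset <- function(data, dir) {
  stopifnot(inherits(data, "occu_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(site_id = data$site_ids, data$y),
                   file.path(dir, "y.csv"), row.names = FALSE)
  if (!is.null(data$W))
    utils::write.csv(data.frame(site_id = data$site_ids, data$W,
                                check.names = FALSE),
                     file.path(dir, "W.csv"), row.names = FALSE)
  for (nm in names(data$det_covs))
    utils::write.csv(data.frame(site_id = data$site_ids, data$det_covs[[nm]]),
                     file.path(dir, sprintf("detcov_%s.csv", nm)),
                     row.names = FALSE)
  meta <- data$meta
  meta$year <- data$year
  # as.list keeps names of length-1 vectors through JSON unboxing
  meta$std <- if (!is.null(data$std))
    list(means = as.list(data$std$means), sds = as.list(data$std$sds),
         quadratic = data$std$quadratic)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a detection dataset written by [write_detection_dataset()]
#'
#' @param dir Directory containing `y.csv` and `meta.json`.
#' @return An `occu_data` object.
#' @export
read_detection_dataset <- function(dir) {
  ytab <- utils::read.csv(file.path(dir, "y.csv"), check.names = FALSE)
  site_ids <- as.character(ytab$site_id)
  y <- as.matrix(ytab[, -1, drop = FALSE])
  storage.mode(y) <- "integer"
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  W <- NULL
  if (file.exists(file.path(dir, "W.csv"))) {
    wtab <- utils::read.csv(file.path(dir, "W.csv"), check.names = FALSE)
    W <- as.matrix(wtab[, -1, drop = FALSE])
  }
  det_covs <- list()
  for (f in list.files(dir, pattern = "^detcov_.*\\.csv$")) {
    nm <- sub("^detcov_(.*)\\.csv$", "\\1", f)
    tab <- utils::read.csv(file.path(dir, f))
    det_covs[[nm]] <- as.matrix(tab[, -1, drop = FALSE])
  }
  std <- meta$std
  if (!is.null(std)) {
    std$means <- unlist(std$means); std$sds <- unlist(std$sds)
  }
  year <- meta$year %||% NA_integer_
  meta$std <- NULL; meta$year <- NULL
  occu_data(y = y, W = W, det_covs = det_covs, site_ids = site_ids,
            year = year, std = std, meta = meta)
}
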