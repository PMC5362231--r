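rec_row <- function(site, date, species)
  data.frame(site_id = site, date = as.Date(date), species = species,
             stringsAsFactors = FALSE)

test_that("minimum-years site filter counts distinct years of any species", {
  rec <- rbind(
    rec_row("A", c("2001-05-01", "2005-06-01", "2009-07-01"), "sp1"),
    rec_row("B", c("2001-05-01", "2002-05-01"), c("sp1", "sp2")),
    rec_row("C", "2003-05-02", "sp2"))
  out <- suppressMessages(filter_sites_by_min_years(rec, 3))
  expect_setequal(unique(out$site_id), "A")
  # min_years = 1 is the identity
  out1 <- suppressMessages(filter_sites_by_min_years(rec, 1))
  expect_equal(nrow(out1), nrow(rec))
  expect_warning(suppressMessages(filter_sites_by_min_years(rec, 10)),
                 "no sites")
})

test_that("flight-season restriction is a sharp month window", {
  rec <- rec_row("A", c("2001-03-31", "2001-04-01", "2001-09-30",
                        "2001-10-01"), "sp1")
  out <- suppressMessages(restrict_to_flight_season(rec))
  expect_equal(format(out$date, "%m-%d"), c("04-01", "09-30"))
  # full-year window and already-inside records are identities
  expect_equal(nrow(suppressMessages(restrict_to_flight_season(rec, 1, 12))), 4)
  jul <- rec_row("A", c("2001-07-01", "2001-07-15"), "sp1")
  expect_equal(suppressMessages(restrict_to_flight_season(jul))$date, jul$date)
})

test_that("visits are unique site-dates with distinct-species list lengths", {
  rec <- rbind(
    rec_row("A", "2001-06-01", c("sp1", "sp2", "sp3")),
    rec_row("A", "2001-06-01", "sp1"),     # duplicate record
    rec_row("A", "2001-06-10", "sp2"),
    rec_row("B", "2001-06-01", "sp2"))
  v <- build_visits(rec, 2001, target = "sp1")
  expect_equal(nrow(v), 3)
  a1 <- v[v$site_id == "A" & v$date == as.Date("2001-06-01"), ]
  expect_equal(a1$list_length, 3L)   # distinct species, duplicates ignored
  expect_equal(a1$target_detected, 1L)
  expect_equal(v$list_length[v$site_id == "B"], 1L)
  expect_equal(sum(v$target_detected), 1L)
  expect_error(build_visits(rec, 1999), "no records")
})

test_that("activity-month trimming brackets the target's observed months", {
  dates <- as.Date(c("2001-04-10", "2001-05-10", "2001-06-10", "2001-07-10",
                     "2001-08-10", "2001-09-10"))
  rec <- rbind(rec_row("A", dates, "other"),
               rec_row("A", c("2001-06-15", "2001-08-02"), "tgt"))
  v <- build_visits(rec, 2001, target = "tgt")
  out <- suppressMessages(trim_to_target_activity_months(v, "tgt", 2001))
  expect_true(all(out$month >= 6 & out$month <= 8))
  # visits with target detections are never removed
  expect_equal(sum(out$target_detected), 2L)
  # target seen in April and September: identity
  rec2 <- rbind(rec_row("A", dates, "other"),
                rec_row("A", c("2001-04-02", "2001-09-20"), "tgt"))
  v2 <- build_visits(rec2, 2001, target = "tgt")
  expect_equal(nrow(suppressMessages(
    trim_to_target_activity_months(v2, "tgt", 2001))), nrow(v2))
  # target never seen: the year cannot be fitted
  v3 <- build_visits(rec_row("A", dates, "other"), 2001, target = "tgt")
  expect_error(trim_to_target_activity_months(v3, "tgt", 2001),
               "cannot be fitted")
})

test_that("visit capping removes only non-detections, reproducibly", {
  dates <- as.Date("2001-05-01") + 0:59
  v <- data.frame(site_id = "A", date = dates,
                  week = occufast:::date_to_week(dates),
                  month = as.integer(format(dates, "%m")),
                  list_length = 1L,
                  target_detected = rep(c(1L, 0L), c(5, 55)))
  out <- cap_visits(v, 50, seed = 42)
  expect_equal(nrow(out), 50)
  expect_equal(sum(out$target_detected), 5L)
  # at or under the cap: unchanged
  expect_identical(cap_visits(v[1:50, ], 50, seed = 1), v[1:50, ])
  # seeded thinning is deterministic
  expect_identical(cap_visits(v, 50, seed = 42), out)
  expect_false(identical(cap_visits(v, 50, seed = 43)$date, out$date))
  # more detections than the cap: all detections kept, with a warning
  vd <- transform(v, target_detected = rep(c(1L, 0L), c(55, 5)))
  expect_warning(outd <- cap_visits(vd, 50, seed = 1), "exceed cap")
  expect_equal(nrow(outd), 55)
  expect_true(all(outd$target_detected == 1L))
})

test_that("weekly target proportion is the target share of weekly records", {
  d0 <- as.Date("2001-06-04")  # a single week bucket
  stopifnot(length(unique(occufast:::date_to_week(d0 + 0:4))) == 1)
  rec <- rbind(rec_row(sprintf("S%d", 1:8), d0 + rep(0:3, 2), "other"),
               rec_row(c("T1", "T2"), d0 + 4, "tgt"),
               rec_row("U1", as.Date("2001-07-20"), "tgt"))
  wp <- weekly_target_proportion(rec, "tgt", 2001)
  expect_length(wp, 53)
  wk <- occufast:::date_to_week(d0)
  expect_equal(wp[wk], 2 / 10)
  expect_equal(wp[occufast:::date_to_week(as.Date("2001-07-20"))], 1.0)
  expect_equal(wp[1], 0)   # week with no records
  expect_true(all(wp >= 0 & wp <= 1))
  # distribution variant: share of the target's records per week
  wpd <- weekly_target_proportion(rec, "tgt", 2001, method = "distribution")
  expect_equal(sum(wpd), 1)
  expect_equal(wpd[wk], 2 / 3)  # 2 of the 3 target records fall that week
  expect_equal(wpd[occufast:::date_to_week(as.Date("2001-07-20"))], 1 / 3)
})

test_that("standardisation uses the sample-sd convention and is invertible", {
  s <- standardise_covariates(cbind(a = c(1, 2, 3), b = c(5, 1, 0)))
  expect_equal(s$W[, "a"], c(-1, 0, 1))
  expect_equal(colMeans(s$W), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(s$W, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  # idempotence
  s2 <- standardise_covariates(s$W)
  expect_equal(s2$W, s$W, tolerance = 1e-12)
  # invertibility through the stored constants
  back <- sweep(sweep(s$W, 2, s$sds, `*`), 2, s$means, `+`)
  expect_equal(unname(back[, 1]), c(1, 2, 3))
  expect_equal(apply_standardisation(cbind(a = c(1, 2, 3), b = c(5, 1, 0)), s),
               s$W, tolerance = 1e-12)
  expect_error(standardise_covariates(cbind(a = 1:3, k = c(2, 2, 2))), "k")
})

test_that("assembled datasets respect the pipeline contracts end-to-end", {
  cfg <- record_sim_config(n_sites = 60, n_species = 6, n_years = 4,
                           visit_rate = 8, seed = 31)
  rec <- simulate_opportunistic_records(cfg)
  covs <- data.frame(site_id = sort(unique(rec$site_id)))
  set.seed(1); covs$elev <- rnorm(nrow(covs)); covs$temp <- rnorm(nrow(covs))
  ds <- suppressMessages(assemble_detection_dataset(
    rec, target = "sp04", year = 2002, site_covariates = covs,
    min_years = 2, quadratic = "elev", seed = 7))

  # every y = 1 corresponds to an actual target record at that site-year
  det_sites <- ds$site_ids[rowSums(ds$y == 1L, na.rm = TRUE) > 0]
  tgt <- rec[rec$species == "sp04" &
               format(as.Date(rec$date), "%Y") == "2002", ]
  expect_true(all(det_sites %in% tgt$site_id))
  # all-zero histories are retained (visited, target unseen)
  n_vis <- rowSums(!is.na(ds$y))
  expect_true(any(n_vis > 0 & rowSums(ds$y == 1L, na.rm = TRUE) == 0))
  # visit covariates present exactly where visits are
  expect_identical(is.na(ds$det_covs$log_list_length), is.na(ds$y))
  expect_true(all(ds$det_covs$log_list_length[!is.na(ds$y)] >= 0))
  wp <- ds$det_covs$week_prop[!is.na(ds$y)]
  expect_true(all(wp >= 0 & wp <= 1))
  # visit cap respected
  expect_true(all(rowSums(!is.na(ds$y)) <= 50))
  # standardised design: mean 0, sample sd 1, quadratic term included
  expect_setequal(colnames(ds$W), c("elev", "temp", "elev_sq"))
  expect_equal(colMeans(ds$W), c(elev = 0, temp = 0, elev_sq = 0),
               tolerance = 1e-10)
  expect_equal(apply(ds$W, 2, sd), c(elev = 1, temp = 1, elev_sq = 1),
               tolerance = 1e-10)
})

test_that("sites visited only outside the activity months become all-NA rows", {
  # target flies June-August; site X is visited (other species) in April only
  rec <- rbind(
    rec_row("X", c("2001-04-05", "2002-04-06", "2003-04-07"), "other"),
    rec_row("Y", c("2001-06-10", "2002-06-11", "2003-06-12"), "other"),
    rec_row("Y", c("2001-06-20", "2002-06-21", "2003-06-22"), "tgt"))
  ds <- suppressMessages(assemble_detection_dataset(rec, "tgt", 2002,
                                                    min_years = 3))
  expect_true("X" %in% ds$site_ids)
  expect_true(all(is.na(ds$y[ds$site_ids == "X", ])))
  expect_false(all(is.na(ds$y[ds$site_ids == "Y", ])))
})

test_that("the pipeline recovers the record generator's ground truth", {
  cfg <- record_sim_config(n_sites = 250, n_species = 8, n_years = 4,
                           visit_rate = 10, seed = 71)
  rec <- simulate_opportunistic_records(cfg)
  occ <- attr(rec, "occupancy")
  # records only ever arise at occupied sites
  for (sp in colnames(occ)) {
    at <- unique(rec$site_id[rec$species == sp])
    expect_true(all(occ[at, sp] == 1L))
  }
  # fitted occupancy index approximates the target's true occupancy rate
  ds <- suppressMessages(assemble_detection_dataset(rec, "sp03", 2002,
                                                    min_years = 2, seed = 1))
  fit <- suppressWarnings(fit_occu(ds, seed = 1))
  truth <- mean(occ[ds$site_ids, "sp03"])
  expect_lt(abs(occupancy_index(predict_psi(fit)) - truth), 0.08)
})

test_that("detection datasets round-trip through the directory writer", {
  rec <- simulate_opportunistic_records(record_sim_config(
    n_sites = 25, n_species = 4, n_years = 3, seed = 8))
  covs <- data.frame(site_id = sort(unique(rec$site_id)))
  set.seed(2); covs$elev <- rnorm(nrow(covs))
  ds <- suppressMessages(assemble_detection_dataset(
    rec, "sp01", 2002, site_covariates = covs, min_years = 1, seed = 3))
  dir <- withr::local_tempdir()
  write_detection_dataset(ds, dir)
  ds2 <- read_detection_dataset(dir)
  expect_equal(unname(ds2$y), unname(ds$y))
  expect_equal(unname(ds2$W), unname(ds$W), tolerance = 1e-12)
  expect_equal(ds2$site_ids, ds$site_ids)
  expect_equal(ds2$std$means, ds$std$means)
  expect_equal(ds2$det_covs$week_prop, ds$det_covs$week_prop,
               ignore_attr = TRUE, tolerance = 1e-12)
})
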