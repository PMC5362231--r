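test_that("site likelihood matches hand values and latent-state enumeration", {
  expect_equal(site_likelihood(c(1, 0), 1, c(0.5, 0.5)), 0.25)
  expect_equal(site_likelihood(c(0, 0), 0.5, c(0.5, 0.5)), 0.625)
  expect_equal(site_likelihood(c(1, 0), 0, c(0.5, 0.5)), 0)
  expect_identical(site_likelihood(c(1, 0), 0, c(0.5, 0.5), log = TRUE), -Inf)

  # exhaustive: all 2^T histories, T <= 4, random parameters
  set.seed(101)
  for (T in 1:4) {
    H <- all_histories(T)
    for (r in 1:25) {
      psi <- runif(1); p <- runif(T)
      for (h in seq_len(nrow(H))) {
        y <- H[h, ]
        expect_equal(site_likelihood(y, psi, p), enum_site_lik(y, psi, p),
                     tolerance = 1e-10)
      }
    }
  }
  # likelihoods over all histories sum to 1 (probability distribution)
  H <- all_histories(3)
  tot <- sum(apply(H, 1, site_likelihood, psi = 0.3, p = c(0.2, 0.5, 0.7)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("the NLL matches an enumeration oracle and is structurally sound", {
  set.seed(7)
  S <- 20; T <- 3
  z <- rbinom(S, 1, 0.6)
  y <- matrix(rbinom(S * T, 1, 0.4), S, T) * z
  y[1, 2] <- NA  # a missing visit
  W <- matrix(rnorm(S), ncol = 1, dimnames = list(NULL, "x"))
  dc <- list(g = matrix(rnorm(S * T), S, T))
  dat <- occu_data(y, W = W, det_covs = dc)
  par <- c(0.3, -0.5, -0.2, 0.4)
  expect_equal(occu_nll(par, dat, "x", "g"),
               enum_nll(par, dat, "x", "g"), tolerance = 1e-10)

  # duplicated data doubles the NLL exactly
  dat2 <- occu_data(rbind(y, y), W = rbind(W, W),
                    det_covs = list(g = rbind(dc$g, dc$g)))
  expect_equal(occu_nll(par, dat2, "x", "g"),
               2 * occu_nll(par, dat, "x", "g"), tolerance = 1e-10)

  # invariance to site reordering and to padding with missing visits
  perm <- sample(S)
  datp <- occu_data(y[perm, ], W = W[perm, , drop = FALSE],
                    det_covs = list(g = dc$g[perm, ]))
  expect_equal(occu_nll(par, datp, "x", "g"), occu_nll(par, dat, "x", "g"),
               tolerance = 1e-12)
  datpad <- occu_data(cbind(y, NA), W = W,
                      det_covs = list(g = cbind(dc$g, 0)))
  expect_equal(occu_nll(par, datpad, "x", "g"), occu_nll(par, dat, "x", "g"),
               tolerance = 1e-12)

  # boundary: all detections, psi -> 1, p -> 1 drives the NLL to 0
  dall <- occu_data(matrix(1L, 10, 4))
  expect_lt(occu_nll(c(20, 20), dall), 1e-6)

  # analytic gradient agrees with numerical differentiation
  ctx <- occufast:::.nll_context(dat, "x", "g")
  fn <- occufast:::.nll_fn(ctx); gr <- occufast:::.nll_gr(ctx)
  num <- vapply(seq_along(par), function(j) {
    h <- 1e-6; e <- numeric(length(par)); e[j] <- h
    (fn(par + e) - fn(par - e)) / (2 * h)
  }, 0)
  expect_equal(unname(gr(par)), num, tolerance = 1e-5)
})

test_that("the intercept-only MLE matches an exhaustive grid search", {
  dat <- sim_constant_data(S = 50, T = 4, psi = 0.6, p = 0.45, seed = 12)
  fit <- fit_occu(dat)
  gs <- grid_mle(dat$y)
  expect_equal(plogis(fit$beta[[1]]), gs$psi, tolerance = 0.002)
  expect_equal(plogis(fit$alpha[[1]]), gs$p, tolerance = 0.002)
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
})

test_that("fitting errors on unfittable data and flags degeneracies", {
  dat <- occu_data(matrix(0L, 30, 3))
  expect_error(fit_occu(dat), "no detections")
  # all-detections data: boundary estimates are flagged, fit still returned
  dall <- occu_data(matrix(1L, 30, 3))
  fit <- suppressWarnings(fit_occu(dall))
  expect_true(fit$flags$boundary || fit$flags$vcov_degenerate)
})

test_that("MLEs recover generating parameters with calibrated uncertainty", {
  # interval calibration: truth within 2 SEs in >= 90% of replicates
  n_rep <- 100
  hits_psi <- hits_p <- 0
  for (r in seq_len(n_rep)) {
    dat <- sim_constant_data(S = 1000, T = 10, psi = 0.6, p = 0.3,
                             seed = 5000 + r)
    fit <- fit_occu(dat, n_starts = 1, seed = r)
    se <- sqrt(diag(fit$vcov))
    hits_psi <- hits_psi +
      (abs(fit$beta[[1]] - qlogis(0.6)) <= 2 * se[1])
    hits_p <- hits_p + (abs(fit$alpha[[1]] - qlogis(0.3)) <= 2 * se[2])
  }
  expect_gte(hits_psi / n_rep, 0.9)
  expect_gte(hits_p / n_rep, 0.9)
})

test_that("slope bias vanishes at large S (3 Monte-Carlo SEs)", {
  n_rep <- 20; S <- 5000
  beta_true <- c(0.4, 0.7)  # intercept, slope on x
  est <- matrix(NA_real_, n_rep, 2)
  for (r in seq_len(n_rep)) {
    set.seed(300 + r)
    x <- rnorm(S)
    z <- rbinom(S, 1, plogis(beta_true[1] + beta_true[2] * x))
    y <- matrix(rbinom(S * 5, 1, 0.35), S, 5) * z
    dat <- occu_data(y, W = matrix(x, ncol = 1, dimnames = list(NULL, "x")))
    fit <- fit_occu(dat, occ_terms = "x", n_starts = 1, seed = r)
    est[r, ] <- fit$beta
  }
  bias <- colMeans(est) - beta_true
  mcse <- apply(est, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(bias) <= 3 * mcse))
})

test_that("predictions follow the logistic links", {
  dat <- sim_constant_data(S = 200, T = 5, psi = 0.5, p = 0.4, seed = 3)
  set.seed(4)
  W <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "x"))
  dat$W <- W
  fit <- fit_occu(dat, occ_terms = "x", seed = 2)

  # all-zero covariate row -> inv-logit(intercept)
  W0 <- matrix(0, 1, 1, dimnames = list(NULL, "x"))
  expect_equal(as.numeric(predict_psi(fit, W0)),
               plogis(fit$beta[[1]]), tolerance = 1e-12)
  # monotone in a covariate with positive/negative coefficient
  Wm <- matrix(seq(-2, 2, length.out = 9), ncol = 1,
               dimnames = list(NULL, "x"))
  psi_m <- as.numeric(predict_psi(fit, Wm))
  if (fit$beta[[2]] > 0) expect_true(all(diff(psi_m) > 0))
  else expect_true(all(diff(psi_m) < 0))
  # zero coefficients give 0.5 everywhere
  fit0 <- fit; fit0$beta <- c(0, 0)
  expect_equal(as.numeric(predict_psi(fit0, Wm)), rep(0.5, 9))
  expect_error(predict_psi(fit, matrix(0, 1, 1,
                                       dimnames = list(NULL, "zz"))),
               "missing covariate")

  # detection: hand-computed 2-visit fixture
  g <- matrix(c(log(1), log(5)), 1, 2)
  fitd <- suppressWarnings(fit_occu(occu_data(matrix(c(1L, 0L), 1, 2),
                                              det_covs = list(g = g)),
                                    det_terms = "g", seed = 1))
  p_pred <- predict_p(fitd, list(g = g))
  expect_equal(as.numeric(p_pred),
               plogis(fitd$alpha[[1]] + fitd$alpha[[2]] * as.numeric(g)),
               tolerance = 1e-12)
  # constant-detection fit: p = inv-logit(detection intercept)
  fitc <- fit_occu(sim_constant_data(100, 4, 0.5, 0.5, seed = 9))
  expect_equal(unique(as.numeric(predict_p(fitc))),
               plogis(fitc$alpha[[1]]))
})

test_that("AIC comparison ranks models and polices dataset identity", {
  set.seed(11)
  S <- 1500; T <- 6
  g <- matrix(rnorm(S * T), S, T)
  z <- rbinom(S, 1, 0.55)
  p <- plogis(-0.8 + 1.2 * g)
  y <- matrix(rbinom(S * T, 1, p), S, T) * z
  dat <- occu_data(y, det_covs = list(g = g, noise = matrix(rnorm(S * T), S, T)))
  f0 <- fit_occu(dat, det_terms = character(), seed = 1)
  fg <- fit_occu(dat, det_terms = "g", seed = 1)
  fn <- fit_occu(dat, det_terms = c("g", "noise"), seed = 1)
  cmp <- aic_compare(list(null = f0, true = fg, overfit = fn))
  # the generating covariate wins decisively over the null on large data
  expect_equal(cmp$delta_aic[1], 0)
  expect_equal(cmp$model[3], "null")
  expect_gt(cmp$aic[cmp$model == "null"] - cmp$aic[cmp$model == "true"], 50)
  # a pure-noise addition moves AIC by at most ~the 2-unit penalty
  d_noise <- cmp$aic[cmp$model == "overfit"] - cmp$aic[cmp$model == "true"]
  expect_gt(d_noise, -2.1)
  expect_lt(d_noise, 4)
  # identical fit twice: delta 0
  cmp2 <- aic_compare(list(a = fg, b = fg))
  expect_equal(cmp2$delta_aic, c(0, 0))
  # different data refused
  other <- fit_occu(sim_constant_data(40, 3, 0.5, 0.5, seed = 2), seed = 1)
  expect_error(aic_compare(list(fg, other)), "identical dataset")
})

test_that("delta-method SEs match closed forms and a Monte-Carlo oracle", {
  dat <- sim_constant_data(S = 400, T = 6, psi = 0.55, p = 0.35, seed = 21)
  fit <- fit_occu(dat, seed = 1)

  # zero covariance -> zero SE
  fit0 <- fit; fit0$vcov <- matrix(0, 2, 2)
  expect_equal(delta_method_se_psi(fit0), rep(0, fit$n_sites))
  # psi = 0.5 with unit linear-predictor variance -> SE 0.25
  fit5 <- fit; fit5$beta <- c(0); fit5$vcov <- diag(2)
  fit5$occ_terms <- character()
  W0 <- matrix(numeric(0), 1, 0)
  expect_equal(as.numeric(delta_method_se_psi(fit5, W0)), 0.25)

  # Monte-Carlo oracle: sd of inv-logit over coefficient draws
  se <- delta_method_se_psi(fit)[1]
  set.seed(9)
  draws <- occufast:::rmvnorm_eigen(1e5, fit$beta, fit$vcov[1, 1, drop = FALSE])
  expect_equal(se, sd(plogis(draws[, 1])), tolerance = 0.05)
})
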