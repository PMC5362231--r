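# Bespoke data-augmentation MCMC for the Bayesian random-effects
# occupancy model ("model B"): logit(psi_it) = b_t + u_i with
# u_i ~ N(0, sigma_u), and detection either constant on the logit scale
# (the simulation-study variant) or logit(p_itj) = a_t + k log(G_itj)
# with a_t ~ N(mu, sigma) when list lengths are supplied. Latent
# occupancy states z_it are Gibbs-sampled; all other parameters use
# random-walk Metropolis within their prior support, with proposal
# scales adapted during burn-in toward 0.44 acceptance and frozen
# afterwards.

#' Prior specification for the random-effects occupancy model
#'
#' Defaults: `b_t ~ U(-10, 10)`, `sigma_u ~ U(0, 5)`, `mu ~ N(0, 10)`
#' (second argument a standard deviation), `sigma ~ U(0, 5)`,
#' `k ~ U(-10, 10)`, and for the constant-detection variant
#' `logit p ~ U(-10, 10)`. The simulation study widens the random-effect
#' prior to `sigma_u ~ U(0, 25)`.
#'
#' @param b,sigma_u,sigma,k,logit_p Length-2 bounds of uniform priors.
#' @param mu Mean and sd of the Normal prior on the detection hyper-mean.
#' @param mu_sd_is_variance Interpret `mu[2]` as a variance instead of an
#'   sd.
#' @return An object of class `model_b_priors`.
#' @export
model_b_priors <- function(b = c(-10, 10), sigma_u = c(0, 5),
                           mu = c(0, 10), sigma = c(0, 5),
                           k = c(-10, 10), logit_p = c(-10, 10),
                           mu_sd_is_variance = FALSE) {
  for (nm in c("b", "sigma_u", "sigma", "k", "logit_p")) {
    v <- get(nm)
    stopifnot(length(v) == 2, all(is.finite(v)), v[1] < v[2])
  }
  mu_sd <- if (mu_sd_is_variance) sqrt(mu[2]) else mu[2]
  structure(list(b = b, sigma_u = sigma_u, mu = c(mu[1], mu_sd),
                 sigma = sigma, k = k, logit_p = logit_p),
            class = "model_b_priors")
}

#' MCMC configuration
#'
#' Defaults follow the reference chain settings: 3 chains of 10,000
#' iterations, the first 20% discarded as burn-in, thinning by taking
#' every third iteration (2667 stored draws per chain).
#'
#' @param n_chains,n_iter,burn_in_fraction,thin,seed Chain settings.
#' @param adapt Adapt proposal scales during burn-in.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 10000,
                        burn_in_fraction = 0.2, thin = 3, seed = 1,
                        adapt = TRUE) {
  stopifnot(n_chains >= 1, n_iter > 1, burn_in_fraction >= 0,
            burn_in_fraction < 1, thin >= 1,
            n_iter * (1 - burn_in_fraction) > thin)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in_fraction = burn_in_fraction, thin = as.integer(thin),
                 seed = as.integer(seed), adapt = isTRUE(adapt)),
            class = "mcmc_config")
}

#' Gibbs draw of a latent occupancy state
#'
#' If the site-year history contains a detection the state is 1 with
#' probability 1; otherwise it is Bernoulli with the posterior
#' probability of occupancy given an all-zero history,
#' `psi prod(1-p) / (psi prod(1-p) + 1 - psi)`.
#'
#' @param y 0/1/NA detection history for one site-year.
#' @param psi Occupancy probability.
#' @param p Per-visit detection probabilities (recycled).
#' @return 0 or 1.
#' @export
sample_z_conditional <- function(y, psi, p) {
  p <- rep_len(p, length(y))
  obs <- !is.na(y)
  if (any(y[obs] == 1)) return(1L)
  q <- prod(1 - p[obs])          # empty product = 1 for unvisited
  pr <- psi * q / (psi * q + 1 - psi)
  stats::rbinom(1L, 1L, pr)
}

# Internal: per-(site,year) sufficient statistics from history list.
.mb_stats <- function(histories) {
  TY <- length(histories)
  S <- nrow(histories[[1]])
  n_obs <- n_det <- matrix(0L, S, TY)
  for (t in seq_len(TY)) {
    y <- histories[[t]]
    n_obs[, t] <- rowSums(!is.na(y))
    n_det[, t] <- rowSums(y == 1L, na.rm = TRUE)
  }
  list(S = S, TY = TY, n_obs = n_obs, n_det = n_det,
       det_any = n_det > 0L, visited = n_obs > 0L)
}

#' Fit the random-effects occupancy model by MCMC
#'
#' @param histories List of site x visit 0/1/NA matrices, one per year
#'   (all years share the site set), or a `sim_dataset`.
#' @param list_lengths Optional list of site x visit list-length matrices
#'   (same shapes). When supplied, detection is modelled as
#'   `logit(p) = a_t + k log(G)`; otherwise detection is constant on the
#'   logit scale.
#' @param priors A [model_b_priors()].
#' @param config An [mcmc_config()].
#' @return An object of class `model_b_chains`: per-chain stored draws of
#'   the parameters and of the annual occupied proportion
#'   (`index`, the mean of the latent states over all sites), plus
#'   acceptance rates.
#' @export
fit_model_b <- function(histories, list_lengths = NULL,
                        priors = model_b_priors(),
                        config = mcmc_config()) {
  if (inherits(histories, "sim_dataset")) histories <- histories$histories
  stopifnot(is.list(histories), length(histories) >= 1,
            inherits(priors, "model_b_priors"),
            inherits(config, "mcmc_config"))
  st <- .mb_stats(histories)
  use_ll <- !is.null(list_lengths)
  logG <- if (use_ll) lapply(list_lengths, log)
  obs_mask <- if (use_ll) lapply(histories, function(y) !is.na(y))

  burn <- as.integer(floor(config$burn_in_fraction * config$n_iter))
  store_at <- seq.int(burn + 1L, config$n_iter, by = config$thin)
  par_names <- c(sprintf("b[%d]", seq_len(st$TY)), "sigma_u",
                 if (use_ll) c(sprintf("a[%d]", seq_len(st$TY)), "mu",
                               "sigma", "k") else "logit_p")

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$seed, ch))
    chains[[ch]] <- .mb_run_chain(histories, st, logG, obs_mask, use_ll,
                                  priors, config, burn, store_at, par_names)
  }
  structure(list(chains = chains, par_names = par_names,
                 n_years = st$TY, n_sites = st$S, config = config,
                 priors = priors, use_list_length = use_ll,
                 store_at = store_at),
            class = "model_b_chains")
}

.mb_run_chain <- function(histories, st, logG, obs_mask, use_ll,
                          priors, config, burn, store_at, par_names) {
  S <- st$S; TY <- st$TY
  # Initial state: z = 1 wherever ambiguous (avoids absorbing starts).
  z <- matrix(1L, S, TY)
  b <- numeric(TY)
  sigma_u <- min(1, mean(priors$sigma_u))
  u <- stats::rnorm(S, 0, min(0.1, sigma_u))
  lp <- min(max(0, priors$logit_p[1] + 1e-9), priors$logit_p[2] - 1e-9)
  a <- numeric(TY); mu <- 0
  sigma <- min(1, mean(priors$sigma)); kk <- 0
  sc <- list(b = 0.2, u = 1.2, sigma_u = 0.3, lp = 0.1, a = 0.2,
             mu = 0.3, sigma = 0.3, k = 0.1)
  acc <- lapply(sc, function(x) c(0, 0))   # accepted, proposed

  # Cached logit-occupancy surface for the current (b, u); the site-year
  # occupancy loglik is log(1-psi) + z*eta, so caching eta and log(1-psi)
  # makes z-, u- and b-updates each cost one plogis call at most.
  ETA <- matrix(b, S, TY, byrow = TRUE) + u
  L1P <- stats::plogis(-ETA, log.p = TRUE)
  det_loglik_total <- function(lp_val) {
    p_log <- stats::plogis(lp_val, log.p = TRUE)
    q_log <- stats::plogis(-lp_val, log.p = TRUE)
    sum(st$n_det * p_log) + sum(z * (st$n_obs - st$n_det) * q_log)
  }
  det_loglik_year <- function(t, a_t, k_val) {
    eta <- a_t + k_val * logG[[t]]
    y <- histories[[t]]
    ll <- ifelse(obs_mask[[t]],
                 ifelse(is.na(y) | y == 1L,
                        stats::plogis(eta, log.p = TRUE),
                        stats::plogis(-eta, log.p = TRUE)), 0)
    sum(ll[z[, t] == 1L, ])
  }

  n_store <- length(store_at)
  draws <- matrix(NA_real_, n_store, length(par_names),
                  dimnames = list(NULL, par_names))
  index <- matrix(NA_real_, n_store, TY,
                  dimnames = list(NULL, sprintf("I[%d]", seq_len(TY))))
  s_row <- 1L

  for (it in seq_len(config$n_iter)) {
    ## (i) Gibbs draw of z
    psi <- exp(ETA + L1P)
    if (use_ll) {
      log_q <- matrix(0, S, TY)
      for (t in seq_len(TY)) {
        pe <- a[t] + kk * logG[[t]]
        lq <- stats::plogis(-pe, log.p = TRUE)
        log_q[, t] <- rowSums(ifelse(obs_mask[[t]], lq, 0))
      }
    } else {
      log_q <- st$n_obs * stats::plogis(-lp, log.p = TRUE)
    }
    num <- psi * exp(log_q)
    pr <- num / (num + 1 - psi)
    pr[!st$visited] <- psi[!st$visited]
    z <- matrix(stats::rbinom(S * TY, 1L, pr), S, TY)
    z[st$det_any] <- 1L

    ## (ii) site random effects, vectorised one-site-at-a-time Metropolis
    u_prop <- u + stats::rnorm(S, 0, sc$u)
    ETA2 <- ETA + (u_prop - u)
    L1P2 <- stats::plogis(-ETA2, log.p = TRUE)
    ll_now <- rowSums(L1P + z * ETA) + stats::dnorm(u, 0, sigma_u, log = TRUE)
    ll_prop <- rowSums(L1P2 + z * ETA2) +
      stats::dnorm(u_prop, 0, sigma_u, log = TRUE)
    take <- log(stats::runif(S)) < ll_prop - ll_now
    if (any(take)) {
      u[take] <- u_prop[take]
      ETA[take, ] <- ETA2[take, ]
      L1P[take, ] <- L1P2[take, ]
    }
    acc$u <- acc$u + c(sum(take), S)

    ## (ii) year effects b_t (conditionals factor over years)
    b_prop <- b + stats::rnorm(TY, 0, sc$b)
    ETA2 <- ETA + matrix(b_prop - b, S, TY, byrow = TRUE)
    L1P2 <- stats::plogis(-ETA2, log.p = TRUE)
    inb <- b_prop > priors$b[1] & b_prop < priors$b[2]
    ll_now <- colSums(L1P + z * ETA)
    ll_prop <- colSums(L1P2 + z * ETA2)
    take <- inb & log(stats::runif(TY)) < ll_prop - ll_now
    if (any(take)) {
      b[take] <- b_prop[take]
      ETA[, take] <- ETA2[, take]
      L1P[, take] <- L1P2[, take]
    }
    acc$b <- acc$b + c(sum(take), TY)

    ## (iii) sigma_u
    s_prop <- sigma_u + stats::rnorm(1, 0, sc$sigma_u)
    if (s_prop > max(priors$sigma_u[1], 1e-6) && s_prop < priors$sigma_u[2]) {
      lr <- sum(stats::dnorm(u, 0, s_prop, log = TRUE)) -
        sum(stats::dnorm(u, 0, sigma_u, log = TRUE))
      if (log(stats::runif(1)) < lr) {
        sigma_u <- s_prop
        acc$sigma_u <- acc$sigma_u + c(1, 1)
      } else acc$sigma_u <- acc$sigma_u + c(0, 1)
    } else acc$sigma_u <- acc$sigma_u + c(0, 1)

    ## (ii)/(iii) detection parameters
    if (!use_ll) {
      lp_prop <- lp + stats::rnorm(1, 0, sc$lp)
      if (lp_prop > priors$logit_p[1] && lp_prop < priors$logit_p[2]) {
        lr <- det_loglik_total(lp_prop) - det_loglik_total(lp)
        if (log(stats::runif(1)) < lr) {
          lp <- lp_prop
          acc$lp <- acc$lp + c(1, 1)
        } else acc$lp <- acc$lp + c(0, 1)
      } else acc$lp <- acc$lp + c(0, 1)
    } else {
      for (t in seq_len(TY)) {
        a_prop <- a[t] + stats::rnorm(1, 0, sc$a)
        lr <- det_loglik_year(t, a_prop, kk) - det_loglik_year(t, a[t], kk) +
          stats::dnorm(a_prop, mu, sigma, log = TRUE) -
          stats::dnorm(a[t], mu, sigma, log = TRUE)
        ok <- log(stats::runif(1)) < lr
        if (ok) a[t] <- a_prop
        acc$a <- acc$a + c(ok, 1)
      }
      k_prop <- kk + stats::rnorm(1, 0, sc$k)
      if (k_prop > priors$k[1] && k_prop < priors$k[2]) {
        lr <- sum(vapply(seq_len(TY), function(t)
          det_loglik_year(t, a[t], k_prop) - det_loglik_year(t, a[t], kk), 0))
        ok <- log(stats::runif(1)) < lr
        if (ok) kk <- k_prop
        acc$k <- acc$k + c(ok, 1)
      } else acc$k <- acc$k + c(0, 1)
      mu_prop <- mu + stats::rnorm(1, 0, sc$mu)
      lr <- sum(stats::dnorm(a, mu_prop, sigma, log = TRUE)) -
        sum(stats::dnorm(a, mu, sigma, log = TRUE)) +
        stats::dnorm(mu_prop, priors$mu[1], priors$mu[2], log = TRUE) -
        stats::dnorm(mu, priors$mu[1], priors$mu[2], log = TRUE)
      ok <- log(stats::runif(1)) < lr
      if (ok) mu <- mu_prop
      acc$mu <- acc$mu + c(ok, 1)
      sg_prop <- sigma + stats::rnorm(1, 0, sc$sigma)
      if (sg_prop > max(priors$sigma[1], 1e-6) && sg_prop < priors$sigma[2]) {
        lr <- sum(stats::dnorm(a, mu, sg_prop, log = TRUE)) -
          sum(stats::dnorm(a, mu, sigma, log = TRUE))
        ok <- log(stats::runif(1)) < lr
        if (ok) sigma <- sg_prop
        acc$sigma <- acc$sigma + c(ok, 1)
      } else acc$sigma <- acc$sigma + c(0, 1)
    }

    ## adaptation during burn-in only
    if (config$adapt && it <= burn && it %% 50L == 0L) {
      for (nm in names(sc)) {
        if (acc[[nm]][2] == 0) next
        rate <- acc[[nm]][1] / acc[[nm]][2]
        sc[[nm]] <- max(1e-3, sc[[nm]] * exp(rate - 0.44))
        acc[[nm]] <- c(0, 0)
      }
    }

    if (s_row <= n_store && it == store_at[s_row]) {
      draws[s_row, ] <- c(b, sigma_u,
                          if (use_ll) c(a, mu, sigma, kk) else lp)
      index[s_row, ] <- colMeans(z)
      s_row <- s_row + 1L
    }
  }
  rates <- vapply(acc, function(x) if (x[2] > 0) x[1] / x[2] else NA_real_, 0)
  list(draws = draws, index = index, acceptance = rates, scales = sc)
}

#' @export
print.model_b_chains <- function(x, ...) {
  cat(sprintf("Random-effects occupancy model MCMC: %d chain(s), %d stored draws each\n",
              length(x$chains), nrow(x$chains[[1]]$draws)))
  cat(sprintf("  %d sites, %d years, detection: %s\n", x$n_sites, x$n_years,
              if (x$use_list_length) "a_t + k log(G)" else "constant"))
  invisible(x)
}

#' Split-chain potential-scale-reduction diagnostic
#'
#' Standard split-R-hat: each chain is halved, and between/within
#' variances compared across the resulting sequences.
#'
#' @param draws_list List of numeric vectors, one per chain.
#' @return The R-hat value.
#' @export
split_rhat <- function(draws_list) {
  halves <- unlist(lapply(draws_list, function(v) {
    n <- floor(length(v) / 2)
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary of the annual occupancy index
#'
#' Pools the stored draws of the annual occupied proportion across
#' chains and summarises them; optionally summarises the percent change
#' in the index between two named years over the draws.
#'
#' @param chains A `model_b_chains` object.
#' @param change_years Optional length-2 vector of year indices for the
#'   percent-change summary.
#' @param probs Quantiles to report.
#' @return List with `index` (per-year data.frame of mean/sd/quantiles),
#'   `params` (same for model parameters, plus split-R-hat),
#'   and optionally `percent_change`.
#' @export
posterior_index_summary <- function(chains, change_years = NULL,
                                    probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(chains, "model_b_chains"))
  idx <- do.call(rbind, lapply(chains$chains, `[[`, "index"))
  par <- do.call(rbind, lapply(chains$chains, `[[`, "draws"))
  summarise <- function(m) {
    qs <- t(apply(m, 2, stats::quantile, probs = probs, names = FALSE))
    colnames(qs) <- sprintf("q%g", 100 * probs)
    data.frame(mean = colMeans(m), sd = apply(m, 2, stats::sd), qs)
  }
  out <- list(index = cbind(year = seq_len(chains$n_years),
                            summarise(idx)))
  pr <- summarise(par)
  pr$rhat <- vapply(seq_len(ncol(par)), function(j)
    split_rhat(lapply(chains$chains, function(ch) ch$draws[, j])), 0)
  out$params <- cbind(parameter = colnames(par), pr)
  if (!is.null(change_years)) {
    stopifnot(length(change_years) == 2)
    pc <- (idx[, change_years[2]] - idx[, change_years[1]]) /
      pmax(idx[, change_years[1]], .Machine$double.eps) * 100
    out$percent_change <- c(mean = mean(pc),
                            stats::quantile(pc, probs = probs))
  }
  out
}

#' Write MCMC chains to a long-format CSV
#'
#' Columns: `iteration`, `chain`, `parameter`, `value`; index draws are
#' included as parameters `I[t]`.
#'
#' @param chains A `model_b_chains`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_chains_csv <- function(chains, path) {
  rows <- lapply(seq_along(chains$chains), function(ch) {
    m <- cbind(chains$chains[[ch]]$draws, chains$chains[[ch]]$index)
    data.frame(iteration = rep(chains$store_at, ncol(m)),
               chain = ch,
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
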