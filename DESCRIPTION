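Package: occufast
Title: Efficient Classical Occupancy Modelling for Opportunistic
    Citizen-Science Records
Version: 0.1.0
Authors@R:
    person("occufast", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits single-season site-occupancy models to detection
    histories derived from opportunistic, presence-only species records.
    Non-detections are inferred from sightings of benchmark species,
    occupancy and detection probabilities are modelled by logistic
    regression on site- and visit-level covariates, and models are fitted
    per year by maximum likelihood with a zero-inflated likelihood.
    Annual and regional occupancy indices carry parametric-bootstrap
    confidence intervals; trends come from weighted linear regression on
    the index. A data-augmentation MCMC sampler for the Bayesian
    random-effects alternative, a scenario simulator and a simulation
    harness support validation of both approaches, and per-year occupancy
    and standard-error surfaces can be exported as portable map stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
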