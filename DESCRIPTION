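Package: dlnafilter
Title: Linear Noise Approximation Filtering and Inference for Stochastic
    Oscillators with Distributed Delays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Filtering and Bayesian parameter inference for stochastic
    biochemical reaction networks whose hazards depend on a distributed
    (Gamma) delay of past states. Implements an extended Kalman-Bucy
    filter built on the linear noise approximation that propagates the
    joint Gaussian law of the full delay window of unobserved states and
    revises the whole window at each observation, yielding a closed-form
    marginal likelihood, one-step predictive moments and a partial
    smoothing density. Ships a delayed stochastic simulation algorithm, a
    transcriptional negative-feedback (circadian mRNA) model with Hill
    repression, delayed-acceptance adaptive MCMC on the log scale, and
    calibration diagnostics (predictive coverage, posterior predictive
    simulation, standardized residuals, residual periodicity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
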