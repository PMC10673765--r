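Package: channeluq
Title: Ensemble-of-Protocols Uncertainty Quantification for Ion Channel
    Model Discrepancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates Markov-state ion channel currents under voltage-clamp
    protocols, calibrates kinetic models to synthetic data by multi-start
    global optimisation, and quantifies predictive uncertainty due to model
    discrepancy with spread-of-prediction intervals built from an ensemble of
    per-protocol parameter estimates.  Includes cross-protocol validation
    matrices, conductance-restricted (profile-likelihood style) fits, two
    synthetic discrepancy case studies for hERG/IKr kinetics, and a
    two-exponential toy example with Bayesian posteriors via adaptive
    Metropolis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
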