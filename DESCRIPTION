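Package: drate
Title: Double-Robust Estimation of Risk Differences with Monte Carlo
    Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of the average treatment effect (1-year mortality
    risk difference) for a binary exposure and binary outcome in
    population-based cancer epidemiology, with four estimators (naive
    regression adjustment, inverse-probability-of-treatment-weighted
    regression adjustment, augmented inverse-probability weighting, and
    targeted maximum likelihood estimation with a cross-validated super
    learner), influence-curve-based inference, an AIC/BIC best-fit model
    selector, a structural (DAG-based) synthetic cohort generator with
    controllable near-positivity violations, and a Monte Carlo harness
    reporting bias, relative bias, RMSE and confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pracma,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    readr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
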