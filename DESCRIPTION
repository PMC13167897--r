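Package: discboost
Title: Component-Wise Gradient Boosting for Discrete Failure Time Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variable selection and estimation for discrete-time survival
    models with a logistic hazard, time-varying covariate effects represented
    by reduced B-spline expansions, and two-way covariate interactions under
    user-chosen (strong, weak, or no) hierarchy constraints. Implements a
    component-wise gradient boosting procedure that never expands the data
    into long format, two BIC-based stopping rules (an approximate hat-matrix
    boosting BIC and a penalized-refit BIC), penalized Newton re-estimation
    with P-spline or smoothing-spline penalties and TIC smoothing selection,
    delta-method hazard-ratio curves, a simulation engine for discrete
    logistic hazards with autoregressive covariates, and selection and
    estimation accuracy metrics over replicated experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
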