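Package: stddm
Title: Starting-Time Drift Diffusion Models for Value-Based Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulate and fit starting-time drift diffusion models (stDDM) to
    choice and response-time data from mixed lottery tasks. Provides a
    synthetic-task generator with calibrated stimulus statistics, first-passage
    time densities for piecewise-constant-drift Wiener diffusion, hierarchical
    Bayesian estimation by adaptive Metropolis-within-Gibbs, model comparison
    by DIC and split-half cross-validated choice RMSE, and behavioral analyses
    of expected-value sensitivity (logistic slopes, aligned-rank-transform
    factorial ANOVA, posterior contrasts with highest-density intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
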