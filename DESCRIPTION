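Package: ordstar
Title: Ordinal Geo-Additive Regression for Areal Household Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits cumulative-link (probit or logit) structured additive
    regression models for ordinal outcomes observed over administrative
    zones, combining linear covariate effects, penalized B-spline (P-spline)
    smooths, intrinsic Gaussian Markov random field and tensor-product
    spatial effects, and i.i.d. Gaussian zone effects.  Smoothing variances
    are estimated by an empirical-Bayes penalized-likelihood scheme with
    Fellner-Schall restricted maximum likelihood updates; models are
    compared by generalized cross-validation.  Includes tools for
    food-consumption-score level coding, longitudinal mean imputation,
    global Moran's I tests with permutation inference, BayesX-style '.gra'
    contiguity-graph input/output, hot/cold-spot zone classification, and a
    calibrated synthetic panel generator for method checking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    splines,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mgcv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
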