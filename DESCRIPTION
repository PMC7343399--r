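Package: fidtrait
Title: Observer-Tolerance Personality Analysis from Flight-Initiation-Distance Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates constrained-envelope flight-initiation-distance (FID)
    trial data with known among-individual structure and analyses it with
    Bayesian log-normal mixed models: univariate models for visual orientation
    distance (VOD) and FID with correlated individual random slopes and a date
    intercept, a bivariate model sharing one individual-level block across both
    responses, enhanced-agreement repeatability (ICC) with highest density
    intervals, the among-individual VOD-FID correlation (convergent validity),
    per-individual conditional modes, PSIS-LOO pointwise predictive accuracy
    with Pareto k-hat screening, and log-score stacking of predictive
    distributions to weigh individual identity. Includes a behavioral-response
    classification framework for inferring the threat level that approaching
    observers represent, and an end-to-end simulate-fit-decompose-compare
    pipeline with reproducible artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
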