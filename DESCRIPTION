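Package: nbreg
Title: Net-Benefit Regression for Cost-Effectiveness Analysis with
    Robust Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Patient-level cost-effectiveness analysis through net-benefit
    regression (NBR). Fits the linear regression of the per-subject net
    benefit (willingness-to-pay times effectiveness minus cost) on a
    treatment indicator and covariates by ordinary least squares and by
    five outlier-resistant procedures: Huber, Hampel and Tukey-bisquare
    M-estimation, MM-estimation with an S-estimation start, and fast
    least trimmed squares. Provides the one-sided test of
    cost-effectiveness, regression- and bootstrap-based probabilities of
    cost-effectiveness, cost-effectiveness acceptability curves, and a
    Monte-Carlo harness for empirical size and power of the test under
    cost-outlier contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
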