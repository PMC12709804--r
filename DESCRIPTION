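Package: essbasket
Title: Effective Sample Size for Information Borrowing in Bayesian Basket Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the degree of information borrowing in Bayesian basket
    trials through a mean-squared-error based effective sample size (ESS). Fits
    the binomial Bayesian hierarchical model by Markov chain Monte Carlo,
    computes MSE-based and variance-ratio ESS at both the design and analysis
    stages, and implements ESS-based borrowing strategies (model selection on
    negative ESS, the calibrated hierarchical model with empirical-Bayes
    between-group variance, and a similarity-weighted power prior), together
    with a simulation engine for operating characteristics (type I error,
    power, MSE) and calibration of decision thresholds and tuning parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rjags,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
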