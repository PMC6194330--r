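Package: painf
Title: Autoinformation and Partial Autoinformation for Symbolic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Diagnoses the Markov order of finite-alphabet time series the way
    the partial autocorrelation function diagnoses autoregressive order.
    Implements the autoinformation function (time-lagged mutual information)
    and the partial autoinformation function (conditional mutual information
    removing intermediate values), plug-in estimators for joint entropy,
    entropy rate and active information storage, permutation-surrogate
    confidence bands, likelihood-ratio (Kullback) Markovianity tests of orders
    0-2, and a surrogate-based conditional-entropy Markov-order test. Ships
    the validation processes these tools are exercised on: arbitrary-order
    Markov chains, edge-emitting hidden Markov machines (even process,
    golden-mean presentations), single-site 2D Ising Gibbs dynamics, a
    thresholded double-well Langevin ion-channel model, and autoregressive
    processes with ACF/PACF estimation.
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
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
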