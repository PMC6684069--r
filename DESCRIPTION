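Package: cpgnet
Title: Phase-Connectivity and Spectral Model Selection for Central Pattern
    Generator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the coupling structure of central pattern
    generator (CPG) networks from multichannel rhythmic burst recordings.
    Implements a phase-connectivity analysis (Hilbert analytic signal,
    Poincare-section burst-onset detection, k-means small-unit filtering,
    mean-resultant-vector coupling criteria and a coupling likelihood) and a
    complementary spectral model-based analysis: a linear stochastic
    oscillator network is fitted to empirical cross-spectral densities,
    candidate coupling architectures are compared by Laplace-approximated
    log evidence with Bayesian model selection, and condition-dependent
    coupling changes (e.g. after cutting intersegmental connectives) are
    estimated. A seeded synthetic-data generator produces burst recordings
    from ground-truth coupled-oscillator networks so the whole pipeline is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
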