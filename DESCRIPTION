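Package: bgcausal
Title: Causal Connectivity of Thalamus-Basal Ganglia BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-series causal discovery for region-of-interest BOLD panels
    from the basal ganglia motor circuit. Implements block-structured
    preprocessing (nuisance regression, discrete-cosine high-pass filtering,
    per-subject centering, Gaussian-smoothed block concatenation), PCMCI+
    causal discovery under three conditional-independence regimes (partial
    correlation, Gaussian-process regression with distance correlation on
    residuals, and nearest-neighbour conditional mutual information with a
    local permutation scheme), block-shuffle permutation significance, and a
    triangulation scheme that classifies each detected relationship by nature
    (linear, non-linear, complex), lag class, and causal role. A seeded
    synthetic-data module generates multi-subject ROI panels from known
    ground-truth causal graphs so every stage is testable end to end.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
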