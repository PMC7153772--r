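Package: ehgforest
Title: Preterm-Delivery Recognition from Electrohysterogram Signals with
    Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for recognizing preterm delivery from
    abdominal electrohysterogram (EHG) recordings made before versus after
    the 26th gestational week. Reads TPEHG-style WFDB or plain CSV records,
    band-limits and trims the analysis channel, extracts 31 linear and
    nonlinear features (amplitude, spectral, symlet-5 wavelet subband,
    autoregressive, time reversibility, Lyapunov exponent, sample entropy,
    correlation dimension), compares preterm and term groups with
    Mann-Whitney U tests, balances classes with ADASYN oversampling, and
    evaluates a random-forest classifier under stratified six-fold
    cross-validation with out-of-bag permutation feature importance. A
    seeded synthetic-cohort generator emulates the cohort structure so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pROC,
    ranger,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
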