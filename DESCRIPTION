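Package: eegcsp
Title: Common Spatial Patterns and Laplacian Mask Features for Two-Group EEG Classification
Version: 0.1.0
Authors@R:
    person("EEG", "Methods Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for separating two groups of subjects (e.g. Parkinson's
    disease patients and healthy controls) from multi-channel EEG recorded
    under an auditory oddball paradigm.  Implements zero-phase least-squares
    FIR band-pass filtering, onset-centered epoching, pooled group-average
    intervals, Common Spatial Patterns (CSP) fitting with log-variance
    features and informative-channel ranking, small/large surface-Laplacian
    mask features on a 2-D electrode grid, a classical per-band baseline
    feature set (sample entropy, RMS, median and peak frequency), and a
    fixed-split classifier evaluation harness (SVM, naive Bayes, LDA, QDA,
    decision tree) reporting accuracy, sensitivity and specificity.  A
    synthetic two-group EEG cohort generator with planted spatial structure
    makes the whole pipeline testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
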