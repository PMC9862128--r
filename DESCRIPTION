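Package: gafid
Title: ECG Biometric Identification with Gramian Angular Field Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A closed-set biometric identification pipeline for single-lead
    electrocardiogram (ECG) recordings. Raw recordings are cleaned (DC
    removal, zero-phase band-pass filtering), split into fixed-length
    windows, and encoded as Gramian Angular Summation Field (GASF) images:
    each window is rescaled, mapped to polar angles via the arccosine, and
    expanded into the matrix of cosines of pairwise angle sums, optionally
    after piecewise aggregate approximation (PAA). A VGG-style convolutional
    classifier (implemented natively with Rcpp/Armadillo) is trained on the
    images and scored with closed-set identification metrics: accuracy,
    confusion matrix, false acceptance rate (FAR), false rejection rate
    (FRR) and their ratio K. A synthetic multi-subject, multi-activity ECG
    cohort generator (sum-of-Gaussians PQRST beat model with heart-rate
    variability, baseline wander, powerline interference and sensor noise)
    makes the whole pipeline runnable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
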