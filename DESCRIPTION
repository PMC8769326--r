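Package: noctcough
Title: Nocturnal Cough Detection and Sleep-Stage Cough Analysis from Audio
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects cough sound events in whole-night audio recordings and
    analyses them against a sleep-stage hypnogram. Implements adaptive
    energy-histogram thresholding for sound-event detection, segmentation of
    each event into explosive/intermediate/voiced cough phases, a
    34-dimensional acoustic feature set (MFCC, LPC variance, voiced
    autocorrelation scores, zero-crossing rate, entropy, spectral centroid and
    distribution moments), sequential forward feature selection, Gaussian
    mixture and feed-forward neural-network classifiers scored by
    log-likelihood ratios, evaluation utilities (confusion metrics, Cohen's
    kappa, ROC/PR curves, subject-wise cross-validation), and
    duration-normalised cough-rate analysis per sleep stage. A seeded
    synthetic nocturnal-audio generator with ground-truth annotations and
    hypnograms makes every stage testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
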