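Package: dstrf
Title: Deep Network Estimation and Locally Linear Interpretation of
    Sensory Receptive Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits linear and nonlinear encoding models of sensory neural
    responses to an auditory spectrogram stimulus, including a ridge
    spectrotemporal receptive field (STRF), linear-nonlinear and
    short-term-plasticity cascades, and a small convolutional network
    trained with a combined mean-squared-error and correlation loss.
    Trained rectifier networks are interpreted exactly as dynamic
    (stimulus-dependent) spectrotemporal receptive fields (DSTRFs) via the
    input Jacobian, with jackknife significance masking, and the resulting
    receptive-field series is summarised by nonlinearity metrics:
    complexity, gain change, temporal hold and shape change, plus
    receptive-field subtype clustering by the gap statistic.  Includes a
    synthetic-data module with known ground-truth nonlinear neurons and
    noise-corrected evaluation of prediction accuracy on repeated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
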