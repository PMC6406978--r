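Package: sleepcnn
Title: Sleep Stage Classification from Polysomnography with a 1D
    Convolutional Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end automated sleep staging from raw polysomnography
    (PSG) signals. Reads EDF/EDF+ recordings and hypnogram annotations,
    segments signals into labelled 30-second epochs, merges the six
    Rechtschaffen-Kales stages (W, S1-S4, REM) into two- to six-class
    schemes, scales epochs to the unit interval, and trains a 19-layer
    one-dimensional convolutional neural network on single-channel EEG,
    single-channel EOG, or their two-channel combination. The network
    and its training loop (Adam with inverse-time learning-rate decay,
    softmax cross-entropy) are implemented in compiled code; evaluation
    reports confusion matrices with per-class precision, sensitivity and
    F1. A seeded synthetic PSG generator with stage-dependent spectral
    signatures makes the whole pipeline runnable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
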