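Package: runfatigue
Title: Running Fatigue Stage Classification from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for staging running-induced fatigue (pre/mid/post) from
    body-worn 9-axis inertial measurement units (IMUs). Provides a synthetic
    multi-site gait signal generator, Butterworth low-pass conditioning and
    quaternion Kalman orientation estimation, constant-length sliding-window
    dataset construction with configurable overlap and 72/18/10 splitting,
    five reference deep classifier architectures (single- and dual-layer
    LSTM, CNN, LSTM with scaled dot-product attention, and an LSTM/CNN
    fusion model) with exact trainable-parameter accounting, and a
    reproducible training/evaluation pipeline reporting accuracy and
    confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet
Config/testthat/edition: 3
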