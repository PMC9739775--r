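Package: epiwindow
Title: Window-Length Evaluation for EEG Epilepsy Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how the epoching window length affects the
    accuracy of automatic epilepsy detection from single-channel EEG.
    Reads five-class (Z/O/N/F/S) recordings in the plain-text Bonn
    dialect or simulates Bonn-like datasets, low-pass filters them with
    a linear-phase FIR filter, cuts 50%-overlap epochs for window
    lengths of 1-24 s, and extracts a seven-dimensional feature vector
    (mean, median, variance, and delta/theta/alpha/beta spectrum
    amplitudes). Classifiers are a single-hidden-layer sigmoid network
    trained by BFGS with Armijo line search, by multistart global
    optimization, or by a modified real-coded genetic algorithm, plus
    k-nearest neighbours; all are scored by repeated stratified k-fold
    cross-validation across the window-length sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    class,
    e1071,
    optparse
Config/testthat/edition: 3
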