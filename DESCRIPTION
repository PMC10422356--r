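Package: iatr
Title: Instance-Based Adaptive Template Reconstruction for Classification
    of Limited and Non-Stationary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-phase instance-based classifier that reconstructs
    class templates element by element: a training phase retains, per
    feature dimension, the instance values with the largest mean
    between-class distance, and a matching phase re-selects template and
    query elements with the smallest mutual distances before a
    nearest-template majority vote.  Designed for small, noisy training
    sets and non-stationary time series such as EEG, where session-to-
    session drift (template ageing) degrades conventional nearest-
    neighbour matching.  Includes a wavelet-packet variance feature
    pathway for single-channel EEG, an image flattening/rotation-
    augmentation pathway, synthetic data generators (Gaussian class
    clusters, session drift, band-limited signals, parametric toy
    images), and biometric evaluation tools (CMC curves, DET curves,
    equal error rate, cross-validated identification experiments) with a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
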