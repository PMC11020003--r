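Package: drspec
Title: Diffuse Reflectance Spectroscopy Tissue Classification Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end toolkit for classifying tissue from diffuse
    reflectance spectroscopy (DRS) measurements. Provides white/dark
    reference calibration, resampling onto a fixed analysis grid,
    standard-normal-variate (SNV) normalisation, robust median-absolute-
    deviation outlier rejection, shape-based spectral feature extraction
    with haemoglobin-saturation unmixing, Boruta all-relevant feature
    selection, a five-layer 1D convolutional network (SpecNet) plus
    classical baseline classifiers under patient-wise stratified
    cross-validation, HSV-based optical marker segmentation with
    constant-velocity Kalman tracking, and a graduated green-to-pink
    probability colourmap overlay. Ships a synthetic-data module that
    emulates 450-1000 nm colorectal tissue reflectance spectra and
    marker-on-tissue video with known ground truth, so the whole pipeline
    is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    stats,
    utils,
    grDevices,
    pracma,
    ranger,
    xgboost,
    e1071,
    nnet,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
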