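Package: seismoHR
Title: Heart-Rate Estimation from Six-Axis Seismocardiography with 1-D
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates heart rate from chest-worn six-axis motion sensors
    (tri-axis accelerometer plus tri-axis gyroscope, seismocardiography and
    gyrocardiography). Provides the full pipeline: a synthetic paired
    chest-motion/ECG session simulator with programmable heart-rate profiles,
    posture drift and gait harmonics; cubic-spline resampling to 256 Hz,
    Savitzky-Golay motion-artifact subtraction and per-window normalization;
    Pan-Tompkins QRS detection for ground-truth labels from ECG;
    label-preserving data augmentation (permutation, jittering, scaling);
    1-D VGG-style convolutional regression networks (VGG-11/13/16/19 adapted
    to 1 x 1280 x 6 windows) trained with Adam and best-validation
    checkpointing, plus their two-member ensemble; and evaluation by relative
    accuracy, MAE/SDAE/RMSE, Pearson correlation, Bland-Altman limits of
    agreement and the A-Test structural-risk procedure over repeated
    heart-rate-stratified z-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    arrow,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'augment.R'
    'ecg-label.R'
    'evaluate.R'
    'nn-engine.R'
    'model.R'
    'preprocess.R'
    'utils.R'
    'simulate.R'
    'pipeline.R'
    'seismoHR-package.R'
    'signal-io.R'
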