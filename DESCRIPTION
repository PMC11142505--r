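Package: emglearn
Title: Hybrid Wavelet/EEMD Denoising and Imbalance-Aware Classification of
    Surface EMG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying lower-limb surface electromyography (sEMG)
    recordings from healthy and knee-abnormal subjects. Implements a hybrid
    denoising stage combining level-4 Daubechies-7 wavelet decomposition with
    garrote shrinkage under the universal threshold and ensemble empirical
    mode decomposition (EEMD), a sliding-window time-domain feature bank
    (MAV, RMS, zero crossings, slope sign changes, and related statistics),
    SMOTE oversampling of the minority class, and a leakage-safe stratified
    cross-validation harness over standard machine-learning classifiers.
    Includes a synthetic sEMG generator with controllable contaminants
    (white noise, 50 Hz power-line interference, baseline wander) and
    duration-driven class imbalance, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    rpart,
    randomForest,
    ranger,
    e1071,
    nnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
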