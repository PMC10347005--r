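Package: enoseaug
Title: Feature-Space Data Augmentation and Classifier Benchmarking for
    Electronic-Nose Sensor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements interpolation-extrapolation data augmentation in
    feature space for multichannel electronic-nose voltage signals,
    together with SMOTE, Gaussian-noise and signal-stretching baselines,
    a synthetic rising-response signal generator with controllable class
    separability, four classifier families (multi-layer perceptron,
    multiclass SVM, random forest, PCA+SVM) under a uniform
    train/predict/score contract, and an evaluation harness for repeated
    trainings, augmentation-size sweeps, extrapolation-bound sweeps and
    augmentation-method comparisons on small labelled datasets.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
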