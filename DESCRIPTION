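Package: tab2img
Title: Image-Based Classification of Tabular Clinical Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts tabular clinical records into images of width-modulated
    coloured bars, augments them with elastic distortion and morphological
    operators, and classifies them with a frozen-backbone transfer-learning
    convolutional network. Includes leakage-safe leave-one-out cross-validation
    with fresh per-fold augmentation, hard/soft voting and stacking ensembles
    with a random-forest meta-classifier, a full evaluation suite (precision,
    recall, F1, ROC/AUC, Brier score, calibration curves), and a Gaussian-copula
    generator for prostate-cohort-like synthetic data with mixed continuous and
    ordinal margins.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    randomForest,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
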