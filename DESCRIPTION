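Package: dpforest
Title: Druggable-Protein Prediction with Sequence Descriptors and Cascade Deep Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts druggable proteins from amino-acid sequence. Implements
    three sequence-derived feature encoders (a histogram-of-oriented-gradients
    descriptor over position-specific scoring matrices, a
    composition/transition/distribution physicochemical descriptor, and a
    composite physicochemical sequence representation), serial hybrid feature
    fusion, a cascade deep-forest classifier built from layered heterogeneous
    tree ensembles with out-of-fold class-probability augmentation, and a
    stratified cross-validation evaluation harness with confusion-based
    metrics and ROC/AUC. Includes synthetic sequence and profile generators so
    the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
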