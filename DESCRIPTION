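Package: pocusda
Title: Training-Data Expansion and Evaluation for Point-of-Care Breast
    Ultrasound Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how training-data expansion affects deep
    classifiers of breast ultrasound images across imaging devices. Provides a
    seeded two-domain speckle phantom generator emulating standard cart-based
    and point-of-care (POCUS) B-mode acquisitions; preprocessing (margin crop,
    zero-padding, resizing); per-class histogram specification and histogram
    equalization; spatial and brightness/noise augmentation policies; a compact
    convolutional network and cycle-consistent adversarial domain translation
    (one model for all classes or one per class) built on an internal
    CPU conv-net engine; and an evaluation suite with malignant-vs-rest ROC/AUC,
    a sensitivity-constrained Youden operating point, bootstrap confidence
    intervals, balanced accuracy, Frechet distance between feature Gaussians,
    the paired DeLong test and Holm-Bonferroni stepdown correction. An
    orchestration layer assembles the sixteen canonical training-data
    combinations and produces comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
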