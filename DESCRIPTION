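Package: strainclass
Title: Concussion Classification from Voxel-Wise White-Matter Fiber Strain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking concussion classifiers built on
    voxel-wise white-matter (WM) peak fiber-strain image volumes, as
    produced by finite-element head impact simulation. Provides a
    synthetic strain-volume generator with planted discriminative
    regions and known ground truth; four scalar injury metrics (BrIC,
    CSDM of the whole brain and corpus callosum, and peak
    corpus-callosum fiber strain) with univariate logistic regression;
    F-score and random-forest voting feature selection with cross-fold
    selection probability maps; a fully connected deep network trained
    by ADAM with batch normalization and early stopping, alongside
    linear-SVM and random-forest baselines behind one fit/predict
    contract; and evaluation by leave-one-out cross-validation,
    out-of-bootstrap resampling with the .632+ error estimator, ROC/AUC,
    and randomized-label validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    ranger,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
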