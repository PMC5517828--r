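Package: mciwindows
Title: Time-Window Prognostic Models for MCI-to-Dementia Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds prognostic classification models for conversion from
    mild cognitive impairment (MCI) to dementia from longitudinal diagnosis
    histories and baseline neuropsychological features. Learning examples
    are constructed either with the conventional First-Last design or with
    censoring-aware time windows of k years; models are selected by
    repeated stratified cross-validation with strictly in-fold
    preprocessing (mean/mode imputation, correlation-based feature
    selection, SMOTE oversampling) over a grid of seven classifier
    families, and designs are compared with Wilcoxon, Friedman and McNemar
    tests. A longitudinal cohort simulator with covariate-dependent
    Weibull conversion times provides ground-truth data for testing and
    calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    randomForest,
    glmnet,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
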