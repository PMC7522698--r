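Package: emlscreen
Title: Ensemble Machine Learning Screening from Blood Metabolomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a metabolomics-based cancer
    screening test with an ensemble of ten classifiers whose votes are
    weighted by cross-validation accuracy. Provides a synthetic GC-MS-like
    case-control cohort generator, feature-presence filtering and
    preprocessing for peak-intensity tables, a uniform train/confidence
    interface over ten base classification models, the signed ensemble
    (EC-EML) score, and diagnostic-performance evaluation: confusion-matrix
    screening metrics, ROC analysis with the Youden cutoff, DeLong
    comparison of correlated AUCs, and PLS-DA permutation validation with
    R2Y/Q2Y indices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    randomForest,
    e1071,
    nnet,
    class,
    glmnet,
    mixOmics,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
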