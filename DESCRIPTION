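Package: mvpakit
Title: Cross-Validated Multivariate Pattern Analysis of Neuroimaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scriptable multivariate pattern analysis (MVPA) for volumetric
    neuroimaging data: leakage-safe cross-validated two-class decoding and
    regression on voxel or tabular feature matrices, feature preprocessing
    (Z-scoring, PCA, F-score/weight/LASSO feature selection) fitted on
    training folds only, searchlight information mapping, permutation-based
    inference with max-statistic family-wise-error correction, and multimodal
    data fusion at the feature (concatenation) or decision (confidence-weighted
    voting) level. Results are returned as tibbles with tidy(), glance() and
    autoplot() methods; a configuration-file driven command-line entry point
    reproduces whole analyses from a single saved file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    data.table,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    pROC,
    parallel,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
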