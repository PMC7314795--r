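Package: radharmony
Title: Batch-Effect Harmonization of Radiomic Feature Tables with ComBat
    Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Location-scale harmonization of multicenter radiomic feature
    tables with the empirical-Bayes ComBat family: classic ComBat, the
    reference-anchored M-ComBat, and bootstrap-stabilized B-ComBat and
    BM-ComBat. Includes unsupervised discovery of harmonization labels by
    hierarchical clustering with silhouette-scored selection of the number
    of clusters, a harmonization-quality evaluation battery (per-feature
    ANOVA across labels, aggregate coefficient of variation, principal
    component summaries, balanced accuracy and Matthews correlation
    coefficient), an imbalance-aware machine-learning benchmark harness
    (SMOTE, LASSO-selected logistic regression, random forest and support
    vector machine pipelines with embedded feature selection), and a
    synthetic multicenter data generator with known ground-truth batch
    effects for validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    glmnet,
    randomForest,
    e1071,
    pROC,
    jsonlite
Suggests:
    sva,
    yaml,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
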