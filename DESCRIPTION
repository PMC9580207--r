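Package: mirmark
Title: Ensemble Elastic-Net Feature Screening and Cox Filtering for miRNA
    Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies candidate miRNA biomarkers from subtype-labelled
    expression cohorts with survival follow-up. Trains a bootstrap ensemble
    of elastic-net multinomial logistic regression models on stratified
    train/test divisions chosen by a seeded accuracy search, screens
    features by the frequency of nonzero coefficients across the ensemble
    and by cross-subtype participation, and promotes screened features to
    biomarkers through a multivariate Cox proportional-hazards filter on
    coefficient magnitude and significance. Includes a seeded synthetic
    cohort generator with planted subtype and prognostic signal, Kaplan-
    Meier/log-rank survival utilities, and a shared-split harness for
    comparing classifiers on competing feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071,
    nnet,
    optparse
Config/testthat/edition: 3
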