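Package: mgrtox
Title: Consensus Machine Learning for Rat Multigeneration Reproductive
    Toxicity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for predicting rat multigeneration
    reproductive toxicity of chemicals from molecular-descriptor tables.
    Implements three-stage descriptor selection (sparse-descriptor removal,
    Shannon-entropy filtering, and tree-frequency importance selection),
    seven base classifiers with explicit class-probability contracts
    (decision tree, decision forest, random forest, k-nearest neighbors,
    support vector machine with Platt calibration, linear discriminant
    analysis, and ridge logistic regression), a seven-model majority-vote
    consensus with its own probability model, hyperparameter tuning by
    repeated inner cross-validation maximizing the Matthews correlation
    coefficient, repeated 5-fold cross-validation with seven performance
    metrics, prediction-confidence profiling, sensitivity stratified by
    lowest-observed-adverse-effect level, and a principal-component
    centroid-distance applicability-domain analysis.  Ships a synthetic
    descriptor-table generator emulating the statistical structure of
    Mold2-style descriptor data so the full pipeline is testable without
    proprietary inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    randomForest,
    e1071,
    MASS,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
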