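Package: tcrscreen
Title: Case/Control Screening and Classification of TCR-Beta Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for diagnosing disease status from T-cell
    receptor beta-chain (TCR-beta) repertoire sequencing data. Reads AIRR and
    immunoSEQ-style clonotype tables, computes repertoire diversity indices
    (Shannon, Simpson, inverse Simpson, clonality, V-J combination entropy,
    singleton ratio), screens disease-associated public clonotypes by Fisher's
    exact test on presence/absence across a ladder of P-value cutoffs, builds
    diversity-index, two-dimensional and binary presence feature matrices,
    trains and evaluates a bank of classifiers (ROC/AUC, accuracy, sensitivity,
    specificity), ranks features by tree-based and permutation importance, and
    reduces screened marker panels to minimal core sets via Lasso, recursive
    feature elimination with cross-validation, and greedy backward exclusion.
    Ships a seeded synthetic-cohort generator with planted associated
    clonotypes so the whole pipeline is testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    rpart,
    nnet,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
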