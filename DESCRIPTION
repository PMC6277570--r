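Package: druglikeness
Title: Drug-Likeness Classification with Autoencoder-Pretrained Neural
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for building binary drug-likeness
    classifiers from 2D molecular descriptor matrices. Covers curation of
    SDF compound collections (element whitelist, hydrocarbon and mixture
    removal, InChI-based deduplication within and across classes),
    descriptor-matrix post-processing (error-value rows, constant
    descriptors, z-score standardization), class-imbalance correction by
    minority duplication or SMOTE, a fully connected classifier
    initialized from a greedily pre-trained autoencoder and trained with
    a class-weighted binary cross-entropy loss, selection of the positive
    loss weight at the sensitivity/specificity crossing, five-index
    evaluation (accuracy, sensitivity, specificity, Matthews correlation,
    AUC), stratified split and cross-validation orchestration, and a
    synthetic descriptor-data generator so the whole pipeline is testable
    without proprietary compound databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
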