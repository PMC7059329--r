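Package: bcrpqsar
Title: QSAR Classification Pipeline for BCRP (ABCG2) Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for building binary QSAR classifiers
    of breast cancer resistance protein (BCRP/ABCG2) inhibition from
    heterogeneous activity records. Covers activity-record curation into
    binary labels, molecular descriptor and fingerprint computation with
    near-zero-variance and correlation pre-filters, stratified splitting,
    simulated-annealing wrapper feature selection scored by random forests,
    seven classification algorithms behind one interface with two-stage
    hyper-parameter tuning and consensus models, evaluation by random and
    Tanimoto-cluster cross-validation (global/balanced accuracy, Matthews
    correlation, AUC, cross-entropy residual profiles), a density-based
    applicability domain, permutation feature importance, and
    information-gain fragment enrichment over ring-system decompositions.
    Includes synthetic-data generators that emulate every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    ranger,
    e1071,
    glmnet,
    xgboost,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
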