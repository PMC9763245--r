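Package: hazardatlas
Title: Prognostic Biomarker Hazard Profiles Across Disease Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a disease atlas from prognostic biomarker survival models:
    per-disease ensembles of L2-penalized Cox proportional-hazards models
    weighted by held-out concordance, a biomarker-similarity map of disease
    space with a permutation null and a cross-validated graphical-lasso
    partial-correlation network, UMAP/DBSCAN clustering of hazard profiles
    with grid-searched hyper-parameters, lasso-logistic comorbidity models
    from binary co-occurrence records, and a permutation-baseline cluster
    validation statistic (true-match-rate curves and their trapezoidal AUC).
    Includes a seeded synthetic cohort and EHR generator with planted
    risk-profile archetypes so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    survival,
    glmnet,
    uwot,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    corpcor,
    mclust,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
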