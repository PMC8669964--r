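Package: panelIFS
Title: Multiclass Biomarker Panel Discovery by Boruta, mRMR and Incremental
    Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering compact gene-expression biomarker
    panels that distinguish many sample classes (for example tumor types
    across cancer cell lines). Relevant genes are screened with a
    shadow-feature (Boruta-style) random-forest filter, ranked by
    max-relevance/min-redundancy (mRMR) mutual information, and evaluated by
    incremental feature selection under stratified cross-validation with
    SMOTE class balancing, scored by the multiclass Matthews correlation
    coefficient. Optimal and compact classifiers are selected from the IFS
    curve and human-readable IF-THEN decision rules are extracted from a
    CART tree trained on the compact gene panel. A synthetic multiclass
    expression-data generator with known informative, redundant and noise
    genes makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    data.table,
    ranger,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
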