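Package: metabogdm
Title: First-Trimester Metabolomics Biomarker Discovery for Gestational
    Diabetes Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for untargeted LC-MS plasma
    metabolomics in a nested case-control pregnancy cohort: pooled-QC
    relative-standard-deviation filtering, missingness filtering,
    half-minimum imputation, log transformation, empirical-Bayes batch
    correction, standardization and PCA; per-metabolite logistic
    association with Benjamini-Hochberg false-discovery control; random
    forest biomarker panel enumeration with bootstrap stability selection
    and permutation-null validation; integration of metabolite panels
    with conventional clinical risk factors in logistic prediction
    models; and Fisher-exact pathway over-representation analysis against
    local KEGG-style annotation tables. Includes a seeded synthetic
    cohort generator that emulates the assumed data-generating process
    (batch effects, censoring-type and random missingness, pooled-QC
    technical replicates, planted case-control effects) with ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    ranger,
    stats,
    sva,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
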