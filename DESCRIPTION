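Package: smmsubtype
Title: Genetic Subtyping and Progression Risk Modelling for Smoldering
    Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Consensus binary matrix factorization (BMF) subtyping of
    patient-by-alteration matrices built from driver mutations, copy-number
    alterations and IgH/MYC translocations in smoldering multiple myeloma
    (SMM). Provides the BMF core with a binariness penalty, consensus
    clustering with Ward cuts and K-selection diagnostics (Dice-silhouette,
    factorization residual, variance explained, generalized K-L divergence),
    one-sided Fisher enrichment of cluster features with Benjamini-Hochberg
    control, a random-forest subtype classifier for external cohorts, the
    20-2-20 clinical staging and evolving-biomarker (eMP/eHb) rules, a
    survival layer (Kaplan-Meier, log-rank, Cox, Harrell's C, nested-model
    comparison), and a calibrated synthetic-cohort generator so the whole
    pipeline is testable without restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    randomForest,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
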