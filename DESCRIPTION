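Package: qsarpipe
Title: QSAR Model Validation, Virtual-Screening Enrichment, and MD
    Trajectory Statistics
Version: 0.1.0
Authors@R:
    person("qsarpipe", "developers", email = "qsarpipe@example.org",
           role = c("aut", "cre"))
Description: Tools for small-dataset quantitative structure-activity
    relationship (QSAR) modelling and its validation battery: ordinary
    least-squares multiple linear regression with the standard fit
    statistics, leave-one-out cross-validation (Q2), Golbraikh-Tropsha
    external-validation criteria, Y-randomization, and the leverage-based
    applicability domain (Williams plot data).  Also provides a small
    feed-forward neural-network regressor, early-recognition metrics for
    ranked virtual screens (ROC AUC, BEDROC, RIE, enrichment factors,
    accumulation curves), MM/GBSA energy-component bookkeeping, molecular
    dynamics trajectory statistics (RMSD, RMSF, radius of gyration,
    hydrogen bonds, SASA, coordinate PCA, free-energy landscapes),
    rule-based drug-likeness filters, seeded synthetic-data generators for
    every stage, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
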