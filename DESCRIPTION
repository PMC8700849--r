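Package: prsperf
Title: Discriminative and Prognostic Evaluation of Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate a published polygenic risk score (PRS) in an
    independent case-control cohort: variant matching and allele-oriented
    dosage scoring, control-based standardization, logistic-regression
    validation with Nagelkerke pseudo-R-squared, ROC/AUC with DeLong
    confidence intervals, decile odds ratios, age-at-onset quartile
    discrimination, greedy AUC-based identification of the most relevant
    score variants, and a theoretical prognostic analysis combining
    weighted Youden-index thresholds with residual lifetime incidence
    derived from a life table. Includes a synthetic-data generator that
    emulates the genotype, phenotype, weight-table and life-table inputs
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
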