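Package: drconcord
Title: Multi-Grader Concordance Analysis for Diabetic Retinopathy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for inter-grader agreement in diabetic
    retinopathy (DR) screening with several human graders and a patient-level
    automated grader. Implements the ICDR 5-point per-eye severity scale and
    its compressed 4-point patient-level counterpart, quality-based patient
    exclusion, eye-level consensus by majority with explicit adjudication of
    fully discordant eyes, 3-rater and 4-rater (human plus AI) agreement
    taxonomies, unweighted and weighted Cohen's kappa, grade-distribution
    tables, and a post hoc referable-DR binary analysis. A synthetic
    multi-grader data generator with per-rater confusion matrices and exact
    analytic expectations (kappa and agreement-class probabilities) makes
    every stage testable without access to clinical grade data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
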