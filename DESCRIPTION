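Package: nutriscreen
Title: Nutritional Risk Screening, Brief Dietary Assessment, and
    Diagnostic-Accuracy Validation for Hospitalized Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scoring engines for an adapted Nutritional Risk Screening
    2002 (NRS-2002) instrument and a reduced Patient-Generated Subjective
    Global Assessment Short Form (PG-SGA-SF), as embedded in
    self-screening smartphone tools for hospitalized oncology patients; a
    shortened three-item (rice/meat/milk) estimator of daily dietary
    energy and protein intake with guideline-based requirement comparison;
    diagnostic-accuracy and agreement statistics (sensitivity,
    specificity, predictive values, Cohen's kappa, McNemar's test,
    correlation, paired-difference summaries, validity grading) for
    validating an index screening tool against a dietitian-administered
    reference; and a synthetic-cohort simulator so the full screening,
    assessment and validation pipeline can be exercised end-to-end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    e1071
Config/testthat/edition: 3
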