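Package: tripodscore
Title: Scoring Completeness of Reporting Against the TRIPOD Checklist
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how completely multivariable prediction
    model studies report the items of the TRIPOD (Transparent Reporting of a
    multivariable prediction model for Individual Prognosis Or Diagnosis)
    statement. Ships a machine-readable, versioned TRIPOD checklist with
    study-type applicability and conditionality logic, an element-level
    extraction-record schema with validation and long-CSV/JSON interchange,
    a three-level scoring engine (item, model, publication, and per-item
    across models), cohort summary statistics including an adherence
    regression, and a calibrated synthetic cohort generator so the whole
    pipeline is testable without manual extraction data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
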