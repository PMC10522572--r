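Package: nestcc
Title: Nested Case-Control Analysis of Cumulative Antipsychotic Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for nested case-control pharmacoepidemiology
    studies of cumulative drug exposure and cancer risk: cohort screening with
    an auditable exclusion cascade, incidence-density (risk-set) sampling of
    sex- and age-matched controls with a per-patient reuse cap, cumulative
    exposure computed as the union of prescription intervals with a three-level
    duration-imputation hierarchy, conditional logistic regression for 1:m
    matched sets fitted by Newton-Raphson on the exact conditional likelihood,
    and subgroup, leave-one-out and sensitivity analyses. Includes a synthetic
    electronic-health-record generator with a known true exposure effect so
    every stage is testable without access to the original clinical database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
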