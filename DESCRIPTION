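Package: vigicase
Title: Case/Non-Case Disproportionality Analysis for Spontaneous
    Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection with the case/non-case
    method on spontaneous adverse drug reaction report databases. Provides a
    relational container and readers/writers for report bundles, a minimal
    MedDRA-like terminology with SMQ-driven case selection and ATC utilities,
    descriptive epidemiology tabulations, reporting odds ratio (ROR),
    proportional reporting ratio (PRR) and Yates-corrected chi-square
    statistics with conventional signal thresholds, a contingency-table
    completion oracle for auditing published disproportionality tables, and a
    seeded generator of synthetic report databases with controllable
    drug-event association strengths for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
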