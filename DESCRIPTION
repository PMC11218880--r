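Package: rarwatch
Title: Wrong-Patient Retract-and-Reorder Near-Miss Surveillance and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects wrong-patient retract-and-reorder (RAR) near-miss events in
    computerized provider order entry (CPOE) audit logs, groups orders into
    provider signing sessions, and runs the full association analysis used in
    patient-safety surveillance: contingency-table odds ratios with Wald
    intervals, chi-square and equal-proportion tests, univariable screening,
    multivariable logistic regression with one-vs-rest race encoding,
    mixed-effects sensitivity fits, and monthly trend reporting stratified by
    patient-photograph exposure. Ships a synthetic pediatric inpatient order-log
    generator with injected wrong-patient signings and a ground-truth ledger so
    every stage is testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    lubridate,
    jsonlite,
    ggplot2,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
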