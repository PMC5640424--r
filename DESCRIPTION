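Package: smssaudit
Title: Reliability and Adherence Auditing for Creatinine Self-Monitoring Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits patient self-monitoring of kidney function after
    transplantation by reconciling a creatinine meter's device log against the
    values patients registered in a web-based self-management support system
    (SMSS). Re-implements the SMSS traffic-light feedback engine (orange/red
    alerts when a new value exceeds the rolling five-value baseline by more
    than 15% or 20%), classifies every patient-day into a reliability and
    representativeness taxonomy (reliable, noncorresponding with cause
    attribution, phantom, omission, selection), scores adherence to a
    four-phase measurement schedule, quantifies registration delay, audits
    adherence to system feedback against hospital-contact records, and provides
    paired-mean comparisons and a behavioral cohort simulator with labelled
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    optparse,
    knitr
Config/testthat/edition: 3
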