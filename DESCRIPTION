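Package: switchsignal
Title: Rapid Signal Monitoring of a Biosimilar Switching Policy from
    Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rapid monitoring of a mandatory nonmedical switching
    policy (originator to biosimilar infliximab) using administrative-claims
    shaped tables. Builds a policy cohort and historical comparator cohorts
    from dispensation, visit, hospital and enrollment records; ascertains
    medication and health-service endpoints (nth infliximab dispensation,
    dose escalation, switching, antibiotic and new prednisone use, outpatient
    visits, emergency department visits, hospital discharges and emergency
    admissions); and detects policy-impact signals by comparing daily
    cumulative incidence against the historical average with a binomial
    likelihood-ratio rule (threshold exp(1.96), sustained 30 days). Includes a
    seeded synthetic-claims generator with configurable policy effects so the
    whole pipeline is testable without access to restricted health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
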