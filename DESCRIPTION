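Package: artcost
Title: Retention, Resource Utilization, and Provider Costs for ART Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for retrospective, provider-perspective
    costing of antiretroviral therapy (ART) programs from longitudinal
    clinic records. Classifies patient outcomes (retained, died, lost to
    follow-up) at fixed endpoints using a grace-period lateness rule,
    accumulates per-patient resource utilization (drug patient-months,
    laboratory tests, clinic visits by provider type, months in care),
    derives site-level unit costs (annuity-based capital annualization,
    patient-equivalent allocation of shared fixed costs, per-test and
    per-visit costing, CPI and exchange-rate adjustment), and aggregates
    costs with site-clustered (CR1 sandwich) confidence intervals. Ships
    a calibrated six-site synthetic cohort generator emulating a Zambian
    ART program so every stage is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
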