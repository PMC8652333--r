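Package: oebench
Title: Benchmarking Observed-vs-Expected Background Rate Methods for
    Vaccine Safety Surveillance
Version: 0.1.0
Authors@R:
    person("Observational Safety", "Methods Group", email = "oebench@example.org",
           role = c("aut", "cre"))
Description: Simulation benchmark for historical (background) rate comparison
    methods in vaccine safety signal detection. Generates synthetic
    OMOP-style event tables (persons, observation periods, outpatient
    visits, vaccinations, outcome occurrences) with configurable bias
    mechanisms, computes observed versus expected incidence rate ratios
    under four background-rate designs (unadjusted, age-sex adjusted,
    visit-anchored, and both), synthesizes positive control outcomes at
    known incidence rate ratios by event injection, applies empirical
    calibration with a leave-one-out systematic error model, and evaluates
    type 1 and type 2 error, discrimination (AUC), confidence interval
    coverage, precision, mean squared error, and timeliness under monthly
    data accrual.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
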