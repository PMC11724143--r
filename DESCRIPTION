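Package: bpmicrosim
Title: Patient-Level Microsimulation of Cardiovascular Outcomes Under
    Antihypertensive Treatment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level Monte Carlo simulation of 10-year cardiovascular
    outcomes under guidelines-based antihypertensive strategies (untreated,
    monotherapy, dual therapy at full or reduced persistence). Provides a
    synthetic cohort generator calibrated to published population
    characteristics of patients qualifying for dual blood-pressure-lowering
    therapy, a configurable drug/dose systolic blood pressure effect table,
    a log-linear model relating blood pressure reduction to relative risk,
    a constant-hazard medication persistence model, and a daily-cycle
    discrete-event simulation engine with Kaplan-Meier event rates and
    absolute risk reductions under common random numbers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
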