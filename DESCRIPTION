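Package: bpvcea
Title: Markov Cohort Cost-Effectiveness Analysis of Blood-Pressure-Variability
    Guided Antihypertensive Therapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A six-state Markov cohort model for the cost-utility analysis of
    antihypertensive treatment strategies whose stroke and myocardial-infarction
    transition probabilities are derived from treatment effects on blood pressure
    variability (the standard deviation and coefficient of variation of nocturnal
    systolic blood pressure). Provides rate-to-probability annualization, a
    discounted cohort engine with configurable cycle-reward conventions,
    incremental cost-effectiveness metrics (CER, ICER, net monetary benefit,
    dominance), one-way deterministic sensitivity analysis (tornado tables),
    probabilistic sensitivity analysis with Gamma/Beta parameter sampling and
    cost-effectiveness acceptability curves, and an individual-level
    microsimulation oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
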