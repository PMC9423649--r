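Package: htncea
Title: Cost-Effectiveness of Guideline-Based Hypertension Treatment by
    Markov Cohort Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Societal-perspective cost-effectiveness analysis of
    antihypertensive treatment in a low-income setting. Implements a
    discrete-time Markov cohort model of treated and untreated
    hypertension with cardiovascular event tunnel states, DALY
    accounting under GBD-2010 conventions with multiplicative
    comorbidity adjustment, human-capital productivity-loss costing,
    incremental and average cost-effectiveness ratios, net monetary
    benefit, GDP-multiple willingness-to-pay thresholds, and
    deterministic plus probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves. Ships a documented default
    parameter book and synthetic-data generators so the full pipeline
    runs without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
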