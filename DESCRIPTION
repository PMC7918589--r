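Package: needlecea
Title: Trial-Based Cost-Utility Analysis of Needling Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for trial-based cost-utility analysis of two
    needling interventions (dry needling versus percutaneous needle
    electrolysis) for plantar heel pain. Converts EQ-5D-5L responses to
    utility indices through a supplied value set, imputes missing follow-up
    by last observation carried forward, accrues quality-adjusted life years
    by trapezoidal area under the curve, builds a session-level direct-cost
    model with equipment-amortization scenarios and an overhead uplift,
    performs incremental analysis with dominance classification,
    nonparametric bootstrap of cost-QALY pairs, and computes
    cost-effectiveness acceptability curves. Includes a calibrated
    synthetic-cohort generator so the whole pipeline can be exercised and
    validated without patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
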