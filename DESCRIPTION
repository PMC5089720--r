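Package: clampkin
Title: Tracer Kinetics for the Hyperinsulinemic-Euglycemic Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for hyperinsulinemic-euglycemic clamp
    experiments with primed-continuous [3-3H]glucose tracer and labeled
    (hot-GINF) exogenous glucose. Smooths plasma glucose and tracer
    specific activity by optimal segments, computes whole-body glucose
    disposal (Rd) and endogenous glucose production (EGP) with Steele's
    non-steady-state single-pool equation modified for labeled glucose
    infusion, derives peripheral and hepatic insulin sensitivity indices
    and insulin metabolic clearance rate, and compares groups with t
    tests and two-way ANOVA. Includes a mechanistic clamp simulator
    (single-pool glucose, remote insulin action, PI feedback glucose
    controller, assay noise) that provides ground-truth fluxes for
    validating the estimation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
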