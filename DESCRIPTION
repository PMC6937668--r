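Package: t2dprev
Title: Compartmental Modelling of Type 2 Diabetes Prevention Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Age- and sex-structured deterministic compartmental model of type 2
    diabetes mellitus (T2DM) stratified by overlapping risk factors (obesity,
    smoking, physical inactivity) and physical-activity-intervention status.
    Provides nonlinear least-squares calibration to sex- and age-specific
    prevalence targets, a scenario engine for risk-factor prevalence reduction
    and physical-activity interventions with linear scale-up, averted-burden
    accounting (cases and deaths averted, relative prevalence reductions,
    case-fatality rates), and a synthetic-data generator emulating a young,
    rapidly ageing national population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
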