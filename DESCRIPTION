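Package: cmjfatigue
Title: Countermovement-Jump Force-Plate Analysis for Neuromuscular
    Fatigue Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for monitoring neuromuscular fatigue with the
    countermovement jump (CMJ). Segments vertical ground-reaction-force
    recordings into eccentric and concentric phases, derives centre-of-mass
    kinematics by the impulse-momentum method, computes the standard CMJ
    performance variables (jump height, peak force and power, phase impulses,
    mean powers, phase durations and their ratio), builds time-normalized
    force- and power-time curves, and compares testing sessions with
    repeated-measures ANOVA (Mauchly sphericity test, Greenhouse-Geisser
    correction, Bonferroni post hoc tests, partial eta-squared) and with
    one-dimensional statistical parametric mapping using random-field-theory
    thresholds and supra-threshold cluster inference. Includes a physically
    consistent synthetic CMJ waveform generator for whole-study simulation
    and pipeline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
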