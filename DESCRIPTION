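Package: vergescreen
Title: Simulation and Scoring for VR-Based Fusional Vergence Screening
Version: 0.1.0
Authors@R:
    person("vergescreen", "developers", email = "vergescreen@example.org",
           role = c("aut", "cre"))
Description: A headless, seedable simulator and scoring pipeline for a
    virtual-reality screening protocol of distance horizontal fusional
    vergence. Implements prism-diopter/visual-angle geometry, a parametric
    synthetic-observer model with positive and negative fusional vergence
    amplitude limits, the five-condition balloon-hitting session protocol
    (camera-rotation disparity induction), hitting-deviation and total
    vergence amplitude scoring, paired statistical comparisons with a
    Shapiro-Wilk normality gate, and Simulator Sickness Questionnaire
    summaries. Shot records interchange as plain CSV so externally logged
    sessions can be scored without the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
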