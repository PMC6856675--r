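Package: cvloop
Title: Closed-Loop Lumped-Parameter Cardiovascular Simulation and
    Hypertension Scenario Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-body hemodynamics with a closed-loop
    zero-dimensional (lumped-parameter) model: four time-varying-elastance
    heart chambers, four unidirectional valves, and systemic plus pulmonary
    Windkessel compartment chains. Provides the steady-oscillation protocol
    (long wash-in from fixed initial conditions, final-window analysis),
    waveform metrics (systolic/diastolic/mean values, pressure-volume loop
    stroke work, Laplace wall stress), named hypertension scenarios and
    one- and two-parameter sweeps, first-order dynamic local sensitivity
    analysis by central finite differences, post-processing of clinical
    blood-pressure and aortic-diameter series, and synthetic-data
    generators for end-to-end testing. The model right-hand side is
    implemented in C for use with deSolve's compiled-model interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
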