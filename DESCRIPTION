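Package: cprsim
Title: Scripted CPR Scenario Simulation and Automated Resuscitation
    Performance Metrics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for automated assessment of
    cardiopulmonary resuscitation (CPR) skills on a simulated cardiac-arrest
    patient.  Provides a deterministic scenario state machine with a
    three-regime surrogate hemodynamic kernel (no-flow, CPR-flow,
    post-ROSC), a documented plain-text dialect for the three scenario log
    streams (events, physiology, drugs), an analyzer that extracts the
    standard resuscitation performance variables (no-flow time and
    fraction, time to return of spontaneous circulation, defibrillation
    counts and intervals, drug timing, pre-intubation ventilation rate,
    median cardiac output) together with cohort summaries, a parameterized
    synthetic rescuer-team behavior generator for end-to-end testing and
    parameter-recovery studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
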