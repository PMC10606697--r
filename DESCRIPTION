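Package: mcisim
Title: Discrete-Event Simulation of Hospital Mass-Casualty Incident Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates triaged trauma-patient flow through a resource-constrained
    acute hospital during a mass-casualty incident. A discrete-event engine models
    arrivals, triage, health-score dynamics with progressive re-triage and death,
    and priority-based allocation of staff, rooms and imaging machines. On top of
    the engine the package provides outcome metrics against waiting-time
    benchmarks, sequential replication control, one-way and full-factorial
    scenario sweeps with common random numbers, constrained integer staff-mix
    simulation-optimization, and a response-surface regression toolkit with
    collinearity, PRESS and residual diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    nortest,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
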