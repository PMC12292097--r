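Package: nmdar
Title: Kinetic and Look-Up-Table Models of GluN1/GluN2A NMDA Receptor Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic nine-state Markov kinetic model of the
    GluN1/GluN2A NMDA receptor with co-agonist glycine binding, glutamate
    binding, gating transitions, and a voltage-dependent magnesium block of
    the single-channel conductance. Includes stimulus builders (square
    glutamate pulse trains, synaptic release transients, Poisson event
    trains), a particle swarm optimizer with the composite calibration loss
    used to fit the rate constants, EPSC decay analysis (biexponential fits,
    weighted time constants, full duration at half maximum), and a
    look-up-table surrogate synapse model (LUTsyn) trained against the
    kinetic model for fast event-driven prediction of open probability.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
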