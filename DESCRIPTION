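Package: coopgate
Title: Cooperative Gating of L-Type Calcium Channels and Cardiac Alternans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stochastic and deterministic models of cooperative (coupled)
    gating of clustered L-type Ca(v)1.2 channels in ventricular myocytes.
    Implements a 7-state Markov model of the L-type calcium channel with
    open-count and cleft-calcium dependent coupling factors, a lattice of
    calcium release units (5 local Ca compartments, 100 stochastic ryanodine
    receptors and an LTCC cluster per unit) coupled to a free-running
    membrane potential, and a deterministic whole-cell action-potential and
    calcium-cycling model in which cooperativity enters through the
    activation gate. Includes voltage-clamp, AP-clamp and pacing protocols,
    beat-series analysis (action potential duration, alternans amplitudes,
    Ca-to-voltage coupling slope) and the closed-form two-variable coupled-map
    stability theory used to classify stable, alternans and quasiperiodic
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
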