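Package: tfkinetics
Title: Time-Fractional Kinetics on Free-Energy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Numerical tools for non-Markovian kinetics governed by
    time-fractional equations. Provides Mittag-Leffler function evaluation
    (series, asymptotic and integral-representation routes),
    Grunwald-Letnikov discretizations of Riemann-Liouville and Caputo
    fractional derivatives, a predictor-corrector solver for the
    time-fractional kinetic equation on one-dimensional free-energy
    landscapes, the two-state voltage-gated ion-channel model (equilibrium
    open probability and time-fractional relaxation of the open
    probability), and a lattice time-fractional generalized master equation
    with a detailed-balance transition kernel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
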