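Package: wcgamma
Title: Gamma Oscillations and Self-Feedback Loops in the Wilson-Cowan Model
Version: 0.1.0
Authors@R:
    person("wcgamma", "maintainers", email = "wcgamma@example.org",
           role = c("aut", "cre"))
Description: Simulation and bifurcation toolkit for the two-population
    Wilson-Cowan firing-rate model with excitatory and inhibitory
    self-feedback loops. Provides fixed-step Runge-Kutta integration,
    FFT-based dominant-frequency extraction, one-parameter equilibrium
    continuation with Hopf-point location, two-parameter Hopf-curve
    tracing with Bogdanov-Takens and generalized-Hopf detection,
    first-Lyapunov-coefficient criticality, and a closed-loop
    transfer-function linearization that explains how the two
    self-feedback strengths bidirectionally regulate gamma-band
    (30-80 Hz) oscillation onset and frequency. Includes synthetic
    fixture systems (sinusoids, damped oscillators, Hopf normal forms)
    with closed-form answers used as test oracles, and a command-line
    pipeline that regenerates every analysis dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
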