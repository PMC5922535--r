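Package: critnet
Title: Critically Balanced Network Dynamics and Contrast-Dependent Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of critically balanced neural networks:
    skew-symmetric connectivity matrices with purely imaginary spectra as a
    normal-form model of primary visual cortex.  Builds line and ring
    topologies, computes eigenmode spectra, spatial frequencies and
    dispersion fits, solves forced limit cycles by harmonic balance with a
    damped Newton-Raphson iteration, integrates stimulus-onset transients in
    the rotating frame with a stiff complex-valued solver, and reproduces
    contrast-dependent length-response curves, surround-suppression maps,
    and the two-thirds power-law scaling of response-latency decay constants
    with input strength.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
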