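Package: rtsnoise
Title: Single-Trap Random Telegraph Signal Noise Analysis for
    Nanotransistor Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for random telegraph signal
    (RTS) noise in nanoscale field-effect transistor biosensors. Generates
    gate-voltage-dependent two-level RTS drain-current traces with 1/f
    dielectric-polarization background and white measurement noise,
    recovers trap states from noisy traces with a two-state Gaussian
    hidden Markov model, estimates dwell times and sliding-window trap
    occupancy, and evaluates closed-form models for trap-number noise,
    dielectric-polarization noise, the RTS Lorentzian spectrum, the
    occupancy-factor noise spectrum, and signal-to-noise ratios of
    conventional versus single-trap (occupancy-based) readout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
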