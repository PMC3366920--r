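Package: isakit
Title: Kinetic Modelling and Trace Analysis for A-Type Potassium Currents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the somatodendritic A-type potassium
    current (I_SA) carried by Kv4 channel complexes with DPP6 auxiliary
    subunits. Implements continuous-time Markov gating schemes with
    Q-matrix relaxation analysis, binomial subunit-assembly models for
    mixed DPP6a/DPP6K stoichiometry, a per-subunit Boltzmann-shift model
    of steady-state inactivation, multi-exponential decay and
    recovery-from-inactivation curve fitting, voltage-clamp trace
    arithmetic (scaled-null leak subtraction, prepulse-subtraction
    current isolation, fractional recovery), and a seeded synthetic
    sweep generator for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    Matrix,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
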