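Package: vanthoff
Title: Thermodynamic Analysis of van 't Hoff Plots with Free-Knot Splines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits van 't Hoff plots (ln Keq versus temperature) with natural
    cubic splines whose interior knots move freely, selects among linear and
    reciprocal temperature scales and knot counts by a Bayesian information
    criterion, and extracts temperature-dependent Gibbs free energy, enthalpy,
    entropy and heat-capacity differences for two-state systems such as
    temperature-gated ion channels. Includes replicate-based conversion of
    open probabilities to equilibrium constants with propagated standard
    errors, Q10-based enthalpy estimates, and a synthetic-data generator for
    two-state gating with known thermodynamic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
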