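Package: capsort
Title: Mesoscale Simulation of Cell Sorting on Microstructured Thermoresponsive Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A simulation suite for adhesion-based, label-free cell sorting on
    microstructured thermoresponsive polymer coatings. Provides spherical-cap
    geometry and statistics for characterizing cap-decorated surfaces, a
    synthetic scanning-probe-microscopy height-map generator and analyzer, a
    Metropolis Monte Carlo model of cell adsorption and detachment on
    micropatterned adhesive/repulsive surfaces, and a dissipative particle
    dynamics engine for grafted, cross-linkable thermoresponsive polymer films
    (phase separation, cross-linking, and swelling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
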