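Package: gvbleb
Title: Giant-Vacuole Formation by Inverse Blebbing in Schlemm's Canal
    Endothelial Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained biophysical model of giant-vacuole formation by
    inverse blebbing in Schlemm's-canal endothelial cells. Integrates an
    overdamped Rayleigh-Plesset equation for the vacuole radius coupled to a
    two-regime (cortex/membrane) surface-tension law under exact cell-volume
    conservation, with steady-state and saddle-node bifurcation analysis,
    linear stability classification, an Ostwald-ripening extension for
    multiple competing vacuoles, and seeded parameter-perturbation ensembles
    for robustness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
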