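Package: glycobind
Title: Counterion Condensation and Cooperative Nanocapsule Binding at the
    Cell Glycocalyx
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative models of the interaction between cationic
    nanocapsules and the polyanionic cell glycocalyx.  Implements Manning
    counterion-condensation theory for linear polyelectrolytes (charge
    spacing, Bjerrum length, dimensionless line charge density and
    condensed-charge fraction), a cooperative dose-binding model in which
    condensed counterions suppress nanoparticle binding below a critical
    particle concentration, Hill-type kinetics of intracellular vacuole
    formation, and a decomposition of electric cell-substrate impedance
    sensing (ECIS) traces into a nanoparticle-binding decay and a vacuole
    term.  Includes re-implementations of ImageJ-style image
    quantification (mean/triangle auto-thresholds, frame-difference
    motility, vacuole area per cell, glycan-cluster density) and
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml
Config/testthat/edition: 3
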