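Package: hydroshell
Title: Hydration-Shell Density Analysis for Antifreeze Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ellipsoid-referenced solvent density analysis of protein
    hydration shells from molecular dynamics style configurations.
    Computes distance-resolved water density profiles around a protein
    modeled as an ellipsoid, a fictitious bulk-filled-shell reference
    obtained by overlaying the protein on bulk water configurations and
    removing overlapping molecules, the whole-shell relative density
    increment and partial molar volume, and per-surface (ice-binding
    versus non-ice-binding) local density increments together with
    hydrophobic solvent-accessible surface fractions. Includes a
    synthetic-configuration generator with analytically known density
    structure so every estimator can be validated without running
    molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
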