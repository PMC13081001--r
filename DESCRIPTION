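Package: mdscape
Title: Conformational Landscapes and Solvated Interaction Energy Scoring
    for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics trajectories of
    protein and protein-ligand systems. Provides optimal rigid-body
    superposition (Kabsch), RMSD/RMSF and atom-pair distance observables,
    Cartesian principal component analysis with free-energy-landscape
    construction and minima detection, conformational clustering with
    stable-window selection, grid-based binding-pocket volume estimation,
    geometric hydrogen-bond and residue interaction-fingerprint occupancy
    analysis, and solvated interaction energy (SIE) end-point binding
    free-energy scoring with coefficient calibration. Includes
    synthetic-trajectory generators with known ground truth for validating
    every stage, plus readers and writers for multi-model PDB, XYZ and
    delimited energy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
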