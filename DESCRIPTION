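Package: memiso
Title: Structure and Dynamics of Cis Versus Trans Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for comparing all-cis and all-trans
    phospholipid bilayer simulations of the Pseudomonas putida inner
    membrane. Computes phosphate-to-phosphate thickness and membrane
    volume, grid-based area per lipid by nearest-residue partitioning,
    acyl-chain order parameters, lateral diffusion coefficients from mean
    squared displacements with chunked standard errors, unsaturation kink
    angles, and the depth distribution and surface accessibility of
    double bonds relative to the phosphate plane. Includes a geometric
    cis-trans isomerization operator (180-degree rotation about the
    double bond) and a seeded synthetic bilayer-trajectory generator with
    closed-form ground truth for every metric.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
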