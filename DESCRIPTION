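Package: sasbead
Title: Coarse-Grained Sphere Models and Theoretical Small-Angle Scattering
    Curves
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constrained modelling of small-angle X-ray and neutron
    scattering (SAXS/SANS) data from atomistic structures. Converts PDB
    models into coarse-grained sphere (bead) models by grid transformation,
    adds an explicit hydration monolayer for SAXS modelling, computes
    theoretical I(Q) curves with a sphere-adapted, histogram-accelerated
    Debye equation (with Gaussian beam-smearing corrections for SANS),
    derives Guinier radii of gyration and cross-sectional radii, and scores
    models against experimental curves with a crystallographic-style R
    factor. Sequence-based volume, molecular weight and partial specific
    volume calculations constrain the sphere-model parameters. Includes an
    end-to-end directory analysis workflow and seeded synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
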