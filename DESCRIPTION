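Package: ResidueIEM
Title: Residue Interaction Energy Matrices with Implicit Solvent and
    Conservation Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes pairwise residue-residue interaction energies in
    protein 3D structures with a molecular-mechanics scoring function
    (Lennard-Jones plus point-charge electrostatics) under vacuum,
    distance-dependent-dielectric, or generalized Born (OBC-II) implicit
    solvent models, and assembles them into square interaction energy
    matrices. Also provides residue distance matrices (closest-atom and
    center-of-mass metrics), combined energy/distance views, and
    evolutionary conservation profiles computed as
    Gerstein/Sonnhammer/Chothia-weighted per-column information content
    of a multiple sequence alignment mapped onto structure chains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'structure-io.R'
    'forcefield.R'
    'energetics.R'
    'matrices.R'
    'conservation.R'
    'fixtures.R'
    'pipeline.R'
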