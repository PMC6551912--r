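Package: quatsym
Title: Continuous Symmetry Measures for Protein Quaternary Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the near symmetry and chirality of multi-chain
    protein structures with the Continuous Symmetry Measure (CSM).
    Implements sequence-aware atom equivalence classes, optimal
    class-preserving atom permutations via the Hungarian algorithm, a
    two-level ("many chains") assignment that maps whole peptides onto
    one another, closed-form optimisation of the symmetry axis for a
    fixed permutation, and an alternating axis/permutation solver that
    returns S(G), the optimal axis, the atom permutation and the nearest
    G-symmetric structure for cyclic point groups Cn and Sn (including
    the Continuous Chirality Measure). Includes fixed-width PDB reading
    and writing, a preparation pipeline that harmonises chains (alternate
    locations, hydrogens, missing residues and atoms), a synthetic
    homomer generator with planted symmetry for validation, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'pdb-io.R'
    'structure.R'
    'prep.R'
    'equivalence.R'
    'symmetry.R'
    'hungarian.R'
    'assignment.R'
    'solver.R'
    'synthetic.R'
    'report.R'
    'cli.R'
    'quatsym-package.R'
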