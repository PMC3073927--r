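Package: confabR
Title: Systematic Generation of Diverse Low-Energy Conformers by Torsion Driving
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Systematic conformer generation for small molecules by
    torsion driving. Rotatable bonds are identified from the molecular
    graph, each is assigned a discrete set of allowed dihedral angles
    from a SMARTS-keyed torsion library, and the angle sets are reduced
    by topological 2-fold/3-fold symmetry. The full mixed-radix space of
    torsion assignments is enumerated in pseudorandom order with a
    linear feedback shift register, scored with the MMFF94 forcefield
    (constant bonded terms evaluated once, only torsion, van der Waals
    and electrostatic terms re-evaluated), filtered through an energy
    window and an on-the-fly hierarchical RMSD diversity tree, and
    finished with an exact energy-ordered prune under graph-symmetry
    corrected heavy-atom RMSD. Includes the companion crystal-structure
    recovery evaluator and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    processx,
    ChemmineR,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH (MMFF94 evaluation and SMARTS matching backend).
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'confabR-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'backend.R'
    'cli.R'
    'diversity.R'
    'evaluate.R'
    'fixtures.R'
    'forcefield.R'
    'io.R'
    'perception.R'
    'rmsd.R'
    'search.R'
    'symmetry.R'
    'torsion.R'
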