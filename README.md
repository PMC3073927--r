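# confabR

Systematic generation of diverse low-energy conformers of small molecules,
in R — with the companion crystal-structure recovery evaluator.

## What it does, and for whom

Computational chemistry workflows (docking, pharmacophore search, 3D QSAR)
need *conformer ensembles*: sets of 3D geometries that cover the low-energy
shapes of a flexible molecule. confabR builds such ensembles by **torsion
driving**: it keeps the covalent frame of the input 3D structure fixed and
enumerates every combination of a discrete set of allowed dihedral angles
on the rotatable bonds. Coverage is systematic (every grid point is
visited, in pseudorandom LFSR order, up to a cap) and runs are exactly
reproducible.

The retained ensemble is controlled by two parameters:

* an **energy window** `E_cut` — keep conformers within `E_cut` kcal/mol
  (default 50) of the lowest-energy conformer found, under the MMFF94
  forcefield. Since torsion driving leaves bond-stretch, angle-bend,
  stretch-bend and out-of-plane terms unchanged, only the torsion + van der
  Waals + electrostatic sum is re-evaluated per conformer:
  `E_total = E_const + E_var`, with `E_const` computed once per molecule;
* a **diversity level** `d` — every pair of retained conformers differs by
  at least `d` Å in heavy-atom least-squares RMSD. During generation a
  hierarchical diversity tree (level radii 3.0, 2.0, 1.333, …, `d`) rejects
  near-duplicates with few RMSD evaluations; afterwards an exact
  energy-ordered greedy prune under the **symmetry-corrected RMSD**
  (minimum over graph automorphisms, so e.g. a 180° flip of a
  para-substituted phenyl ring counts as identical) removes anything the
  fast filter let through.

Rotatable bonds are acyclic single bonds with two or more heavy neighbours
on both atoms and no sp-hybridised end; allowed angles come from a
user-replaceable SMARTS torsion library (default: 12 × 30° grid), reduced
by topological 2-fold/3-fold symmetry (a 2-fold × 3-fold combination leaves
only angles < 360/6 = 60°).

## Requirements and installation

R (≥ 4.2) with ChemmineR, igraph, jsonlite, processx, Rcpp/RcppArmadillo,
and `python` with RDKit on the PATH (the MMFF94/SMARTS backend; the package
starts it automatically). Then:

```sh
R CMD INSTALL .
```

Run the test suite with:

```r
testthat::test_dir("tests/testthat", package = "confabR", load_package = "installed")
```

## Worked example

```r
library(confabR)

rec <- readMolecules(fixturePath("butane"))[[1]]
rec$mol
#> MoleculeGraph 'butane': 14 atoms (4 heavy), 13 bonds, 0 ring atoms

res <- generateConformers(rec$mol, rec$conf,
                          SearchOptions(diversity = 0.5, verbose = TRUE))
#> mol=butane rotors=1 total=12 tested=12 lowE=12 stored=4 diverse=2 rmsdEvals=14

for (cf in res$ensemble) print(cf)
#> ConformerRecord: 14 atoms, index 6, rel. energy 0.0000 kcal/mol
#> ConformerRecord: 14 atoms, index 0, rel. energy 17.1481 kcal/mol

writeConformers("butane-confs.sdf", rec$mol, res$ensemble)
```

Reading the log line: butane has one rotatable bond (the central C–C), so
the default library gives a 12-point index space; all 12 grid conformers
were tested and passed the 50 kcal/mol window; the diversity tree stored 4
and the symmetry-corrected prune left 2 mutually diverse conformers, 14
plain-RMSD evaluations in total. The survivors are the anti form (torsion
180°, index 6, the energy reference at 0.0000 kcal/mol) and the eclipsed
0° form (17.1481 kcal/mol above it — rigid driving does not relax the
eclipsed clash, hence the large gap). Each record in the output SDF carries
its relative energy in the `Energy_rel_kcalmol` tag.

The same pipeline is scriptable from a shell via the two thin drivers:

```sh
Rscript inst/scripts/confab.R   --rcutoff 0.5 -i in.sdf -o confs.sdf
Rscript inst/scripts/calcrmsd.R -g confs.sdf -r crystals.sdf -o report.csv
# recovery at 1.0 A: 100%
# recovery at 1.5 A: 100%
# recovery at 2.0 A: 100%
```

`calcrmsd` pairs generated ensembles with reference structures by record
order, reports each molecule's minimum symmetry-corrected RMSD in the CSV,
and prints percent recovery (the fraction of molecules with a conformer
within 1.0/1.5/2.0 Å of the reference).

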