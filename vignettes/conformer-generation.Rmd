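---
title: "Systematic conformer generation by torsion driving"
author: "confabR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systematic conformer generation by torsion driving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Docking, pharmacophore searching and 3D QSAR all need conformer ensembles:
sets of low-energy 3D geometries that between them cover the shapes a
flexible molecule can adopt. confabR generates such ensembles
*systematically* — every combination of a discrete set of allowed torsion
angles is visited — rather than stochastically, so coverage is exhaustive up
to the grid resolution and a run is exactly reproducible. Two knobs define
the ensemble: an energy window `E_cut` (kcal/mol above the best conformer
found; default 50) and an RMSD diversity level `d` (Å; every pair of
retained conformers differs by at least `d` in heavy-atom RMSD).

The method operates on a fixed covalent frame: bond lengths, bond angles and
ring geometries are taken from the 3D input structure and never change. Ring
conformations are therefore *not* sampled — an input with a boat cyclohexane
keeps it — and the input must be a reasonable 3D geometry, not a 2D sketch.

## The pipeline

1. **Rotatable bonds.** All acyclic single bonds where both atoms are
   connected to at least two non-hydrogen atoms (the bond partner counts)
   and neither atom is sp-hybridised. Bonds that merely spin hydrogens
   (methyl, hydroxyl) are excluded; this loses nothing because RMSD is
   computed on heavy atoms only. We apply the sp exclusion with a linearity
   guard (degree ≤ 2), so hypervalent centres such as sulfone sulfur — two
   S=O bonds but a tetrahedral frame — remain rotatable, as they must be.
2. **Allowed angles.** Each rotor is matched against a SMARTS-keyed torsion
   library (`torlib.txt` format: `SMARTS angle angle …` per line, `#`
   comment lines, first match in file order wins; the driven bond is the
   pattern's 2nd–3rd atom pair). Unmatched bonds get the default grid of 12
   angles at 30° spacing. The bundled library (amide and ester cis/trans,
   sp3–sp3 30° grid) carries this package's own defaults and is meant to be
   replaced for serious work; pass `--torlib`/`torlib=` to do so.
3. **Symmetry-fold reduction.** If a rotor ends in an sp2 carbon whose two
   rotation-affected heavy neighbours share a topological symmetry class,
   rotating past 180° revisits indistinguishable states, so the angle set is
   cut to values < 180° (2-fold). An sp3 carbon with three same-class heavy
   neighbours gives a 3-fold cut (< 120°). Folds at the two ends multiply: a
   2-fold meeting a 3-fold leaves only angles < 360/6 = 60°. Symmetry
   classes come from iterative Morgan-style refinement seeded with (element,
   heavy degree, formal charge, ring membership, bond-order sum); the seed
   invariants are a design choice of this package, documented rather than
   universal. Kekulé inputs are normalised by aromaticity perception first,
   so the two Kekulé structures of a ring give identical classes.
4. **Energy.** MMFF94 throughout. Under torsion driving the bond-stretch,
   angle-bend, stretch-bend and out-of-plane terms are identical for every
   conformer of a molecule, so they are evaluated once (`constantTerms`);
   only torsion + van der Waals + electrostatics (`variableEnergy`) are
   recomputed per conformer. Parameterisation and evaluation are delegated
   to RDKit behind a persistent adapter process; Open Babel's independent
   MMFF94 implementation is used in the test suite to cross-check the split
   (agreement ~1e-3 kcal/mol on the fixtures). Electrostatics use the
   adapter's MMFF94 defaults (constant dielectric, buffered Coulomb). The
   MMFF94s variant can be selected per context; plain MMFF94 is the
   default. Molecules the forcefield cannot type are rejected up front.
5. **Greedy seed.** The energy window needs a reference. Starting from the
   input geometry, each rotor in turn — most central first, centrality being
   the bond's heavy-atom graph eccentricity — is set to its
   variable-energy argmin with the others held fixed. Because one pass is
   order-dependent, up to 16 passes are run, permuting the ≤ 4 most central
   rotors in lexicographic order (16 caps 4! = 24 deterministically); each
   pass restarts from the input geometry. Per-torsion argmin uses the
   variable energy (equivalent to total up to the constant shift); angle
   ties take the lowest angle. The best energy found seeds `E_ref`, and if
   the main loop later finds something lower, `E_ref` drops from that point
   on.
6. **Enumeration.** The conformer index space is the mixed-radix product of
   the per-rotor angle counts (first rotor least significant). Indices are
   visited in pseudorandom order via a maximal-length linear feedback shift
   register: the smallest width `k` with `2^k − 1 ≥ N` is chosen from a
   hard-coded table of published primitive-polynomial taps (widths 2–32,
   full period unit-tested), the register starts from state 1, emitted
   values above `N` are skipped, and `v − 1` is the 0-based index — so each
   index appears exactly once with no memory overhead, and runs are
   bit-reproducible. Random order avoids biasing the retained set toward
   the input conformation when the tested count is capped
   (`conformerCap`, default 10^6). Index spaces above 2^32 − 1 are refused;
   molecules that large are outside the tool's intended envelope anyway.
7. **On-the-fly diversity filter.** Retained conformers live in a levelled
   tree whose radii descend from 3.0 Å by a factor 1.5 (3.0, 2.0, 1.333, …)
   truncated before reaching `d`, with `d` appended as the bottom level (a
   1.6 Å cutoff gives 3.0/2.0/1.6); `d ≥ 3` collapses to a single level.
   Sibling nodes at a level differ by at least that level's radius, and the
   first child of a parent holds the parent's own conformer, so descending
   reuses the RMSD already computed. A new conformer follows the first
   sibling within the level radius downwards; if no sibling is within the
   radius it is stored with a chain of single children to the bottom; a
   bottom-level hit within `d` rejects it. Rejections always carry a
   witness (the stored conformer within `d`), never a false negative in
   that sense. Insertion uses the *plain* heavy-atom RMSD (Kabsch
   superposition, proper rotations only — mirror images are distinct
   conformers).
8. **Robust prune.** Conformers in different branches can slip below `d`
   relative to each other. After the loop, the stored set is re-filtered
   against the final `E_ref` (so the output window is exact even when the
   reference dropped mid-search) and pruned with the exact energy-ordered
   greedy filter: sort by relative energy (ties by conformer index), keep a
   conformer iff its minimum *symmetry-corrected* RMSD to everything already
   kept is ≥ `d`. We pin the prune to this exact quadratic filter — any
   accelerating structure must reproduce it unchanged — because it gives a
   well-defined, testable contract.
9. **Symmetry-corrected RMSD.** Topologically equivalent atoms (a
   para-substituted phenyl ring flipped by 180°) inflate a naive RMSD. The
   corrected value iterates over the heavy-atom graph automorphisms
   (element-, charge- and bond-order-preserving) and takes the minimum
   aligned RMSD. Automorphism generators come from igraph's BLISS search on
   a vertex-coloured graph (bond orders encoded as coloured edge-subdivision
   vertices) and are closed under composition up to a cap of 5000; past the
   cap the set is truncated with a warning and the correction degrades
   gracefully (still an upper bound). For speed the main loop uses the
   plain RMSD; the correction is applied in the final prune and in all
   benchmark evaluation.

## A known, deliberate property of the on-line filter

The tree filter discards a conformer the moment it is within `d` of any
*already stored* conformer — in arrival (LFSR) order. The final prune is
energy-ordered, so the pipeline's survivors are *a* maximal diverse
low-energy subset, but not always the one the exact energy-ordered filter
would pick from the full grid: the first-arrived member of a cluster, not
the lowest-energy member, may represent it, and a conformer rejected
against a later-pruned neighbour is not revisited. Butane at `d = 0.5` is a
minimal example: exhaustive filtering keeps the anti form plus the two 90°
forms, while the pipeline (which visits index 0 first) keeps the anti form
plus the 0° form. Every survivor still satisfies the window and the
pairwise-`d` guarantees, and on-grid reference structures are still found
within `d` in our recovery tests. This trade of exact representative choice
for constant-memory streaming is inherent to the on-line design; callers
who need the exact filter at small grid sizes can enumerate and call
`robustPrune` directly.

## Evaluation tools

`minRmsdToReference` / `percentRecovery` / `ensembleStatistics` implement
the standard crystal-recovery benchmark: per molecule the minimum
symmetry-corrected RMSD of the generated ensemble to the reference
conformation; aggregated, the percentage of molecules recovered within
cutoffs of 1.0/1.5/2.0 Å, and medians of conformer counts grouped by
rotatable-bond count (conformer totals are post-symmetry-reduction index
space sizes). The `calcrmsd` driver pairs generated and reference files by
record order with a title cross-check and writes a CSV. If conformational
space were covered perfectly, `d` would bound the minimum RMSD to any
reference whose torsions lie on the grid; the test suite asserts exactly
that bound on constructed on-grid references.

## Numerical choices and degenerate inputs

* Torsions are set by rigid rotation of the smaller fragment (tie broken
  toward the side not containing atom 1) about the bond axis, to within
  1e-6°; bond lengths/angles are preserved to machine precision.
* The reference quadruple of a rotor picks, on each side, the heavy
  neighbour with the highest canonical symmetry-class id (ties: lowest atom
  index) — deterministic, so conformer indices are reproducible.
* Collinear torsion frames (a,b,c or b,c,d) raise `degenerate torsion
  frame`; inputs with all-zero coordinates are rejected as not 3D.
* Kabsch superposition with SVD determinant correction; self-RMSD numerical
  noise is below 1e-6 Å (the documented determinism tolerance).
* Energy ties in the prune order break by conformer index; angle-argmin
  ties in the seed break toward the smaller angle.

## What the bundled fixtures emulate — and what they do not

The embedded structures (butane, ethylbenzene, tert-butylbenzene, biphenyl,
para-difluorobenzene, and a phenyl-sulfone ester analogue) are built
analytically with idealised bond lengths and exactly symmetric rings and
tert-butyl groups, so that symmetry-equivalent torsion settings are
numerically degenerate (within 1e-3 kcal/mol) and ring-flip RMSDs vanish to
machine precision; the sulfone analogue is a forcefield-relaxed embedded
geometry. They exercise every code path at desk scale (grids of 2–20736
points; test ensembles of ≤ 200 conformers). Real drug-like molecules
differ in ways the fixtures deliberately do not model: distorted
experimental geometries, multiple interacting rings, charged centres,
crystal-packing effects. Passing tests therefore demonstrate algorithmic
correctness, not benchmark-level recovery on experimental data; recovery
percentages on a real reference set additionally depend on the torsion
library used and on the MMFF94 implementation's parameter coverage.

## Limitations

* No ring-conformation sampling, no stereochemistry enumeration, no
  post-generation minimisation of each conformer (a 200-step steepest
  descent preparation step is available separately as `relaxStructure`).
* Index spaces beyond 2^32 − 1 conformers are not enumerable.
* The automorphism cap (5000) truncates the symmetry correction for
  pathologically symmetric molecules.
* The MMFF94 adapter requires `python` with RDKit on the PATH; the package
  fails loudly, not silently, when it is missing.
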