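---
title: "Cross-link guided assembly modeling and dynamics analysis with xldyn"
author: "xldyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link guided assembly modeling and dynamics analysis with xldyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xldyn)
```

## The problem

Chemical cross-linking mass spectrometry (CL-MS) covalently tethers pairs
of lysine residues that are close in space and identifies the linked
peptides. Each identification is an upper bound on the distance between
two specific residues, and a set of them is a powerful, if sparse, probe
of how the subunits of a multi-protein assembly are arranged. `xldyn`
implements the computational side of this workflow for assemblies with
homo-oligomeric components (dimers, trimers, and larger symmetric cores):
it turns linker chemistry into distance budgets, maps identified
cross-links onto candidate structural models, scores and filters
rigid-body docking poses against the restraints, clusters the survivors,
and characterises the resulting models' flexibility with standard
trajectory and elastic-network analyses.

## Distance budgets

A cross-link between two lysines constrains their C-alpha atoms to be
within

$$ d_{\max} \;=\; s + 2\,\ell_{\text{side}} + \ell_{\text{dyn}}, $$

where $s$ is the spacer length of the reagent, $\ell_{\text{side}} =
5.5$ Å is the reach of each lysine side chain, and $\ell_{\text{dyn}} =
7.6$ Å allows for backbone dynamics not captured by a static model. The
two registered chemistries are the short carbonyl-diimidazole linker
(CDI, $s = 2.6$ Å, budget $21.2$ Å) and the longer urea-based linker
(DSBU, $s = 12.5$ Å, budget $31.1$ Å). Using two linkers of different
reach brackets the interface geometry: a link satisfied under DSBU but
not CDI localises the pair to the 21–31 Å shell. The comparison against
the budget is inclusive (`<=`), matching the "up to" character of the
bound. Components are user-configurable via `linker_chemistry()`; budgets
are always recomputed from components, never stored.

## Mapping links onto assemblies: ambiguity and the minimum over copies

An identified peptide pair cannot tell *which copy* of a homo-oligomer
reacted. `map_crosslinks()` therefore enumerates every cross-copy
candidate pair for each link and takes the **minimum** C-alpha distance —
the most charitable assignment. This is the right convention for
validation against symmetric assemblies (a link is explained if *any*
copy pair explains it), but it is also the main source of false
satisfaction, which is why restraint counting alone is a weak filter and
is combined with clash screening downstream.

Residue numbers in identification tables follow the precursor protein
sequence; deposited models may be numbered differently. A per-protein
integer offset map reconciles the two explicitly rather than silently.
Links to residues absent from the model are flagged unmappable; they are
excluded from the satisfaction denominator by default but always listed,
and a switch (`count_unmappable = TRUE`) includes them, since published
counts do not always state their convention.

## Docking-pose evaluation

Poses are rigid placements of a ligand assembly in the receptor frame,
typically produced by an external docking engine (pose generation is out
of scope here). `score_pose()` evaluates each pose twice:

* **Restraints** — the number of cross-links whose minimum-over-copies
  C-alpha distance fits its budget. The default acceptance threshold is
  **3 satisfied restraints**: requiring all of them is too strict when
  some links may reflect interactions with other copies of the core, and
  fewer than three leaves the pose orientation under-determined.
* **Clashes** — the number of inter-assembly C-alpha pairs closer than
  3.0 Å, counted against a dedicated core assembly when one is supplied
  (e.g. a full 24-mer core when docking onto its trimer), else against
  the receptor. A C-alpha-level criterion cannot see side-chain overlap,
  but it is fast, depends only on backbone geometry, and zero tolerated
  clashes (`max_clash = 0`) is a conservative default.

Filtered poses are ranked under a fixed total order (satisfied restraints
descending, clashes ascending, pose id lexically) and truncated to the
best 30, making the cut reproducible run-to-run. Survivors are clustered
by Ward's minimum-variance criterion on a feature space of flattened
ligand C-alpha coordinates in the receptor frame — with that choice the
Euclidean row distance is a rigid-motion-meaningful quantity (a pure
translation by $d$ moves a pose $d\sqrt{N}$ in feature space). The
cluster count defaults to 3. Representatives are **medoids** (minimum
summed within-cluster distance, ties to the lowest index), so a
representative is always a real pose that can seed a simulation.

## Trajectory and elastic-network analyses

All distance-based statistics work on multi-model PDB trajectories
sharing one topology.

* **Superposition** is Kabsch least-squares via SVD with the determinant
  correction, so reflections are never returned. `rmsd_series()` fits
  every frame onto the reference before measuring.
* **RMSF** uses the standard two-pass scheme: fit to frame 1, compute the
  mean structure, re-fit to the mean, then measure fluctuations about the
  mean. A frame-1 reference is retained as an option for comparison with
  tools that fluctuate about the start.
* **Native contacts** are residue pairs whose minimum heavy-atom distance
  in the reference frame is within 4.5 Å, with intra-chain pairs
  requiring a sequence separation of at least 3 (closer neighbours are
  trivially in contact). $Q(f)$ is the fraction of those pairs preserved
  in frame $f$ at a tolerance factor of 1.0 on the cutoff; all three
  parameters are configurable because no universal convention exists.
* **Hydrogen bonds** use donor-acceptor (N/O) distance within 3.5 Å and a
  D–H···A angle of at least 120° when hydrogens are present; without
  hydrogens the distance criterion alone applies — the usual fallback for
  heavy-atom models. Occupancy is the fraction of frames satisfying the
  criterion.
* **ANM normal modes** use a C-alpha network with uniform springs
  ($\gamma = 1$, arbitrary units — only eigenvalue ratios matter) between
  pairs within 15 Å. Eigenvalues below $10^{-8}$ of the largest are
  flagged as the rigid-body null space, which must have dimension exactly
  6 for a connected, non-degenerate structure; a disconnected network is
  reported with a warning, not hidden. `mode_trajectory()` animates a
  chosen non-trivial mode sinusoidally over one period.
* **PCA** superposes frames onto their mean (same two-pass scheme),
  decomposes the positional covariance, and reports 3 components by
  default. A deterministic sign convention (largest-magnitude coefficient
  positive) makes projections bit-stable. The full spectrum sums to the
  total superposed variance — an identity the tests assert to $10^{-8}$.

## The synthetic substrate

Every stage is tested against seeded generators rather than downloaded
structures, so the whole test suite is reproducible offline.

`make_toy_assembly()` builds poly-alanine-like chains with minimal
backbone (N, CA, C, O) and a Lys-like anchor every 10th residue, so
anchor counts are closed-form. The default `"helix"` geometry is an
alpha-helical trace folded along a meandering (boustrophedon) axis —
straight legs joined by U-turns that stack layers 20 Å apart. This shape
was chosen deliberately: an unfolded ideal helix has a continuous screw
symmetry, and a smooth single arc has a one-dimensional contact
structure; both let a rigid sequence-shifted placement reproduce planted
restraint patterns. The meander is a compact, genuinely 3-D domain in
which spatially close residue pairs span many sequence offsets, as in a
real fold. Copies are arranged cyclically (C$_n$ about z) by default,
the arrangement of real homo-oligomers; a translational option exists
for simple side-by-side fixtures.

`plant_pose_and_links()` inverts the budget logic to create ground truth:
given a docked placement, true links are sampled from anchor pairs within
budget and false positives from pairs beyond budget + 10 Å. True links
are sampled as a *spatially spread matching* — distinct anchors on both
sides, pairwise at least 30 Å apart in each chain frame — because real
identification sets span an interface across distinct lysines, and links
that share or crowd anchors collapse into a single effective restraint
with little orientation information.

`generate_decoy_poses()` draws uniform random rotations (quaternion
sampling) and translations displaced at least 50 Å from the reference
pose (magnitudes uniform in [50, 100] Å). `simulate_noise_trajectory()`
adds iid per-axis Gaussian noise with a per-atom sigma profile, for which
the expected RMSF is exactly $\sigma\sqrt{3}$ — the closed form used for
parameter recovery — plus an optional rigid "wobble" per frame to
exercise superposition.

### What the planted-pose experiment does and does not show

On the standard scene (receptor trimer of 260-residue domains, stacked
ligand dimer of 200-residue domains, 5 true DSBU links, 2 false ones, 20
decoys per seed), the restraint + clash filter retains exactly the
planted pose across the evaluation seeds used in the test suite. This
rejection is statistical, not geometric: a 31.1 Å budget with six
copy-pair instances per link covers an appreciable fraction of the decoy
displacement shell, so a small residual fraction of random *contact*
decoys (measured at roughly 2 per 1000 across 150 independent seeds)
satisfies three restraints without clashing. No toy geometry can drive
that to zero while keeping the restraints informative — which mirrors the
practical situation: sparse ambiguous restraints shortlist poses, they do
not uniquely determine them, and that is precisely why clash screening,
clustering and downstream simulation remain part of the workflow.
Passing tests on this substrate demonstrate the machinery's correctness
and determinism; they do not demonstrate that three restraints suffice to
dock real proteins.

The generators also do not emulate side-chain chemistry, realistic
conformational sampling, density of lysines on real surfaces, or
identification-level noise other than planted distance violations.

## Numerical choices and problem sizes

* Budget comparisons and contact cutoffs are inclusive; ties in
  truncation and medoid selection break deterministically (pose id, then
  lowest index).
* Altloc resolution keeps the highest-occupancy conformer, ties toward
  label "A"; HETATM records are dropped by default — only protein
  geometry enters any computation in scope.
* The rigid-transform validator requires a proper rotation
  ($|\det R - 1| \le 10^{-9}$); reflections are rejected everywhere,
  including inside Kabsch superposition.
* Generators save and restore the global RNG state, so they are pure
  functions of their arguments and seed.
* Test and acceptance problem sizes: RMSF recovery uses 100-residue
  chains at 2000 frames, where the 5% recovery band comfortably covers
  both sampling noise and the small downward bias from fitting out six
  rigid-body degrees of freedom; oracle comparisons use up to 8 points
  (Ward), 100 instances (Kabsch), and 40–100 nodes (ANM); the docking
  scene uses 10 seeds of 21 poses. These sizes were chosen so that each
  statistical check has a comfortable margin at desk scale.

## Limitations

* Distances are Euclidean C-alpha–C-alpha; solvent-accessible surface
  paths are not computed, so a link through a protein body can appear
  satisfied.
* The clash proxy is C-alpha-level only.
* Published model-level satisfaction counts for specific complexes depend
  on externally generated docking poses, long explicit trajectories and
  deposited coordinates, and are not reproduced here; the pipeline
  reproduces the *procedure*, with its own synthetic ground truth.
* Spectrum-level identification, FDR control, and pose generation belong
  to upstream tools and are out of scope.
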