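---
title: "Methods: FFT-based rigid-body docking of nucleic acids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FFT-based rigid-body docking of nucleic acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
fixtures do and do not establish.

## The model

`nadock` treats the association of two nucleic-acid molecules as a
rigid-body search over the six-dimensional space of relative placements.
The receptor is fixed; a candidate pose of the ligand is a rotation `R`
about the ligand's heavy-atom centroid followed by a translation `t`
restricted to a regular lattice. Three scoring layers act in sequence:

1. **Shape complementarity** on a grid, evaluated for all lattice
   translations of a given rotation at once by FFT cross-correlation.
   Its job is not to find the answer but to nominate a short list of
   translations per rotation that touch the receptor without penetrating
   it.
2. **A knowledge-based pair potential** re-scores the nominated poses
   atom-by-atom and decides which single pose a rotation retains, and
   how retained modes rank globally. Scores are purely ordinal: they
   rank poses and are not binding affinities in physical units.
3. **Greedy ligand-RMSD clustering** converts the ranked mode list into
   a non-redundant model list.

The assumptions are those of every correlation docking method: both
partners are rigid (bound-backbone redocking is the ideal case;
conformational change on binding degrades accuracy), the true complex is
reachable by the sampled rotations and lattice translations, and the
scoring function's global minimum is near the native pose.

## Rotation sampling

Orientation space is covered by the product construction
*axis orientation × in-plane spin*: `N_sphere = floor(4π/δ²)` unit
vectors (δ in radians) are placed by a deterministic generalized-spiral
lattice on the sphere, the first exactly at the +z pole, and each is
combined with `round(360°/δ)` spin angles starting at 0. At the default
δ = 15° this yields 183 × 24 = 4392 rotations; the first element is the
identity. The construction is deterministic — no random number is drawn
anywhere in the sampling path — and the test suite verifies both the
count law at several intervals and empirical coverage: 1000 uniformly
random rotations each find a set member within 1.5 δ.

The published method states only the interval and the count; the spiral
× spin construction is this artifact's normative choice, and matching
the count at 15° is a design constraint, not evidence that the point
sets coincide.

## Grids and the FFT scan

**Receptor field.** A cell is *occupied* when any heavy-atom center lies
within `r_occ = 1.8` Å (heavy-atom van-der-Waals scale) of the cell
center. Occupied cells whose 26 neighbors are all occupied are *core*;
occupied cells whose 6 face neighbors are all occupied are *buried*.
Both carry the core penalty (default −15, the classic correlation
docking convention). Remaining occupied cells form the surface skin and,
together with nearby exterior cells, receive a soft value
`min(1, Σ_c w(d))` summed over skin cells within the kernel cutoff.

Two choices here deserve justification:

- *Buried cells are penalized, not only 26-neighbor core cells.* A
  nucleic-acid strand at 1.2 Å spacing is a thin curved ribbon: eroding
  by the full 26-neighborhood leaves almost no interior (8 cells for an
  8-nt strand), and with no penalized interior the correlation score
  rewards interpenetration over contact — we measured the native pose
  ranking ~669th by shape before this change. Face-neighbor erosion
  leaves a realistic interior (~290 cells) and restores the intended
  behavior. The 26-neighbor core class is still computed, stored, and
  audited by tests.
- *The ligand is digitized with a small radius* (1.05 Å ≈ the cell size)
  in the docking scan, while the receptor keeps 1.8 Å. Dilating both
  partners by the van-der-Waals radius makes their envelopes overlap at
  true contact, so the exact native pose was being eaten by the buried
  penalty. Single-sided dilation is the standard convention of grid
  docking codes; the exposed `digitize()` operation keeps a uniform
  default for both roles, and the driver passes its own ligand radius.

**Kernel.** The default kernel is a decaying Gaussian
`w(r) = exp(−(r/r₀)²)` with `r₀` = one grid spacing and cutoff 2
spacings. The literal printed form of the source method, `~e^{−1/r²}`,
*increases* with distance and vanishes at r → 0, which is implausible as
a decaying contribution but may describe a long-range exterior softening;
it is available behind `kernel = "paper_literal"` (r in grid units,
capped at the cutoff) rather than silently "corrected". Neither form's
true cutoff or normalization is recoverable from the source text.

**FFT.** The correlation `S(t) = Σ_g R[g]·L[g−t]` is computed by
zero-padded forward/inverse transforms. Grid sizes are rounded up to
powers of two (not 5-smooth lengths): the radix-2 transform stays simple
and cache-tuned (butterflies vectorized across the fastest axis), and a
property test pins the result to a direct-summation oracle within 1e-6
relative error, making the length choice numerically irrelevant.
Physical receptor-box padding is unnecessary because padding to
`dim(R)+dim(L)−1` already represents every overlapping pose. Per
rotation, the scan keeps the `top_translations = 10` best offsets
(ties broken by lexicographic (z, y, x) offset), re-scores them with the
pair potential, and retains the lowest-energy one — exactly one mode per
rotation, so a default run retains 4392 modes.

## The pair potential

Heavy atoms map to 21 types: 11 backbone types (phosphate oxygens
merged), 9 base classes (purine/pyrimidine ring N and C, amino N,
carbonyl O, thymine methyl), and a catch-all. DNA reuses the RNA
classes with thymine in uracil's class. Energies live in a symmetric
(type, type, bin) table with 0.5 Å bins to `r_max = 10` Å (the interface
scale); pairs below 2.0 Å receive a fixed +10 clash energy per pair
regardless of the table, because a rigid-body search needs an overlap
guard at sub-grid resolution.

Derivation starts from inverse-Boltzmann statistics,
`E(i,j,b) = −ln[(N_obs+ε)/(N_ref+ε)]` with ε = 0.5 and a
distance-uniform-density reference state (each pair's observed total
spread over bins by shell volume `r_hi³ − r_lo³`). Optional refinement
iterations move energies along the native-minus-decoy count difference
whenever a caller-supplied decoy outscores its native — a deterministic,
documented stand-in for the original double-iterative training, whose
decoy protocol and convergence rule are not published in the source
text. The published trained weights are likewise unavailable, so the
default table is derived at load time from eight synthetic duplexes and
cached; reproducing published parameters is explicitly a non-goal.

## Restraints

Site restraints ("residue X of partner P lies at the interface") are
satisfied when the residue's minimum heavy-atom distance to the partner
is at most the interface cutoff (10 Å); distance restraints cap the
minimum heavy-atom distance between two named residues, a reading robust
to missing atoms that also lets predicted inter-molecular base pairs be
encoded as 6–8 Å constraints. Restraints act on the retained mode set —
filtering before clustering, with a documented fallback to
(violations, energy) ordering when nothing survives — rather than inside
the FFT itself; whether the original server biases sampling or only
filters afterwards is not specified in the source text, and filtering
reproduces the observable behavior at far lower complexity.

## Clustering, output, evaluation

Clustering is the verbatim greedy procedure: the lowest-energy remaining
mode seeds a cluster that absorbs every remaining mode within 5 Å ligand
C4′ RMSD *without superposition* (the receptor frame is shared;
superposing would collapse distinct placements), and the seed is the
representative. Clusters are emitted in creation order, up to 100
models, each a PDB with REMARK 3 score lines plus a TSV score table.

Evaluation takes the interface from the *native* complex (residues with
any heavy atom within 10 Å of the partner), superposes the predicted C4′
atoms of those residues — both partners jointly — onto the native ones
by least squares with proper rotations only, and reports the residual as
IRMSD. Superposing on interface C4′ atoms rather than all C4′ atoms is
the conventional IRMSD reading of the ambiguous phrase "based on the
C4′ atoms"; both are implemented (`superpose_set = "all"`), interface
is the default. A hit is IRMSD strictly below 5.0 Å.

## Synthetic fixtures: what they establish

`build_aform_duplex()` places each residue's atoms on per-atom cylinders
around an ideal helix (twist 32.7°/bp, rise 2.81 Å/bp, C4′ radius
9.4 Å — textbook A-form constants chosen once for realism). Each residue
carries ~17 heavy atoms: the full sugar–phosphate backbone plus a reduced
base skeleton branched by purine/pyrimidine. A sparser 4–5-atom set was
tried first and digitizes to a hollow shell at the stated grid defaults
(no buried cells), which breaks shape discrimination — the denser set is
the minimal one reproducing two properties real complexes have on a
1.2 Å lattice: a penalized interior and cross-strand heavy-atom
clearance (~2.3 Å) above the clash guard.

What a green fixture test establishes: the geometry of every pipeline
stage (counts, symmetries, round trips), the exactness of the FFT scan,
the greedy clustering, the IRMSD machinery, and that the *bound redock*
funnel works end to end — the native pose is re-found at rank 1 from
4392 rotations. What it does not establish: performance on real,
irregular RNA folds; unbound or modeled-structure docking; the quality
of the published trained potential (ours is fixture-derived, and it is
trained on the same geometry family it redocks); or the published
benchmark success rates, which require external structures and weights.

The decoy generator perturbs the ligand by an exact-magnitude rotation
and/or translation and tags each decoy with its exact C4′ RMSD, so
discrimination tests have ground truth by construction.

## Numerical and degenerate-input choices

- Tie-breaks are total and deterministic everywhere: translation ties by
  lexicographic (z, y, x); energy ties by rotation index, then offset;
  identical inputs give bit-identical outputs, including written files.
- Orthonormality of rotations is enforced to 1e-8; superposition rejects
  collinear point sets (second singular value ~0) and never returns
  reflections.
- Hydrogens, waters and ions are stripped at parse time; modified
  residues map through a small alias table (e.g. PSU→U) and unknown
  residue names fail loudly with the offending name.
- Empty restraint sets satisfy everything; an empty interface warns and
  returns empty sets; IRMSD with fewer than 3 interface C4′ atoms is an
  error rather than a number.
- The grid size guard (default 256³ cells) converts pathological inputs
  into an actionable "increase spacing" error.

## Known limitations

- Rigid-body only; no refinement of top models (the upstream server's
  optional minimization step is out of scope).
- The default potential is synthetic-fixture-derived; for real work a
  user should derive a table from curated complexes via
  `derive_potential()` and pass it to `dock()`.
- The pair-energy inner loop is O(n_rec × n_lig) per rescored pose; fine
  for oligonucleotides, noticeable for very large molecules.
- Sequence input, structure prediction, inter-molecular base-pair
  prediction and multi-body docking are out of scope by design.
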