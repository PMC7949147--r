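---
title: "Comparative MD interface analysis: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative MD interface analysis: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdiface)
```

## The problem

Point mutations in a pseudokinase scaffolding domain can destabilize a
protein–protein complex without touching the binding surface, by rewiring
internal hydrogen-bond networks and collective motions (allostery). Given
molecular-dynamics trajectories of a wild-type two-chain complex and of one
or more mutants, `mdiface` quantifies that destabilization along four axes:

1. **Hydrogen-bond occupancy** — the percentage of trajectory frames in
   which a specific donor–H–acceptor interaction satisfies geometric
   criteria. This is the natural statistic for salt bridges (tracked as
   H-bonds between carboxylate oxygens and guanidinium protons), side-chain
   to backbone bonds, and ATP-phosphate contacts.
2. **Interface contact maps and the reduction statistic** — per-residue
   intermolecular contact occupancy between the two chains, and the
   mutant-versus-WT percent reduction, per residue
   (`100 * (1 − occ_mut / occ_wt)`) and overall
   (`100 * (1 − mean mutant contacts/frame / mean WT contacts/frame)`).
3. **Subdomain RMSD** — time-averaged root-mean-square deviation of a
   selection after optimal rigid (Kabsch) superposition, a per-subdomain
   disruption metric.
4. **Trajectory PCA** — eigendecomposition of the Cartesian coordinate
   covariance after removing rigid-body motion; PC1 is the dominant
   collective motion, and its projection histogram is the per-system
   fingerprint compared between WT and mutants.

A fifth, independent module fits cycloheximide-chase turnover series
(`fraction(t) = exp(−k t)`, half-life `ln 2 / k`), connecting the
structural predictions to cellular protein-stability measurements, plus a
small Mendelian utility for the expected fraction of offspring in a
multi-locus cross.

Real production trajectories of this kind (100-ns solvated-complex runs)
are rarely deposited; the package therefore ships seeded synthetic
generators that plant known ground truth with the same statistical
structure, so every analysis stage is validated against a hidden truth
rather than against itself.

## Hydrogen-bond model

A bond is counted in a frame when

* donor heavy atom to acceptor heavy atom distance ≤ `max_da_distance`
  (default **3.0 Å**), and
* donor–hydrogen–acceptor angle ≥ `min_dha_angle` (default **135°**).

These are the conventional cutoffs of standard MD trajectory H-bond
analysis. Both are configurable per run and echoed into every report
header, because published occupancies are only comparable under identical
criteria. Boundaries are **closed** (a pair exactly at a cutoff counts as
bonded) — an arbitrary but fixed tie-break that matters only for synthetic
data placed exactly on a boundary. Donors are N/O heavy atoms with at least
one covalently bonded hydrogen (one donor entry per hydrogen, so a lysine
NZ contributes three); acceptors are all N/O atoms. Structures without
explicit hydrogens are rejected by the H-bond operations (simulation
systems are protonated; crystal structures without hydrogens cannot support
the angle test). Occupancies below 5% are reported but flagged as low.

Composite occupancy over a group of equivalent bonds (e.g. the oxygens of
one phosphate group) has two documented semantics: `"sum"` adds individual
occupancies (may exceed 100%) and `"union"` counts frames with at least one
bond present (≤ 100%). Published composite numbers do not always say which
was used, so both are first-class and the report records the mode.

## Contact maps and the reduction statistic

Contacts default to interface hydrogen bonds (`kind = "hbond"`); van der
Waals heavy-atom proximity (`kind = "vdw"`, default cutoff **4.5 Å**) and
the per-atom-pair union (`"both"`) are available because interface
destabilization can also appear in packing. Per-residue occupancy for the
reduction formula uses **union semantics** — the percent of frames in which
the residue makes at least one interface contact — because a colorimetric
per-residue map needs one number per residue; `"sum"` semantics is a
documented alternative. Three edge rules:

* a residue with zero WT occupancy is **masked** (`NA`), written as 0.00
  with a REMARK in the B-factor PDB, never reported as ±infinity;
* mutant occupancy above WT gives a **negative** reduction, not clamped;
* the overall reduction uses mean contacts per frame, so it is invariant
  to frame order and insensitive to which residues carry the contacts.

## Superposition, RMSD, and PCA

`kabsch_superpose()` computes the optimal proper rotation from the SVD of
the 3×3 cross-covariance with the usual determinant correction (no
reflections). Collinear or pointlike fit sets are rejected as degenerate.
The time-averaged RMSD fits each frame on `fit_selection` and measures on
`measure_selection`, with frame 1 (the experimental starting structure, by
convention) as the default reference; the iterative mean structure is
available as an alternative reference. Subdomain boundaries are user
configuration, never hard-coded: they are a structural-biology judgement,
not a property of the file. Atom choice for subdomain RMSD follows the
selection the user passes (the tests use all atoms of the subdomain; Cα or
heavy-atom selections are one expression away). No mass weighting is
applied by default.

PCA removes rigid-body motion by superposing every frame on the **iterative
mean structure** (fit to mean, re-average, repeat until the mean moves
< `tol`, default 1e-6 Å, guarded at 100 iterations) — covariance about the
mean requires a self-consistent alignment, so frame 1 is not an adequate
target here. The covariance is non-mass-weighted Cartesian; the default
selection is Cα atoms when present, else heavy atoms. The decomposition is
computed from the SVD of the centered frame matrix, which covers both the
3N×3N and the frames×frames regime with identical spectra. Eigenvector
signs are fixed (largest-magnitude element positive) so results are
reproducible run-to-run. One subtlety the test suite documents: under a
global rigid transform of all frames the *eigenvalues* and the
*projections* (up to sign) are exactly invariant, while eigenvectors live
in the rotated alignment frame — asserting eigenvector equality would be
wrong.

PC1 projection histograms are density-normalized over a range symmetric
about zero spanning the observed extremes (default **100 bins**; bin width
is recorded). Two systems are compared by the **histogram-intersection
divergence** `1 − Σ min(density_a, density_b) · bin_width` on shared
binning: 0 for identical distributions, 1 for disjoint support. This
operationalizes the visual "divergent PC1 shape" comparison as a scalar;
eigenvalues are reported alongside so the weight of each component is
available to plots.

## Turnover kinetics

Chase series are normalized as
`fraction(t) = (raw(t)/loading(t)) / (raw(0)/loading(0))`, so every series
is exactly 1 at t = 0 and scale-invariant. The fit is a
**through-origin linear regression of −ln(fraction) on time**
(`k = Σ t·y / Σ t²`), the standard estimator for chase assays whose model
is constrained through (0, 1); nonlinear least squares on the linear scale
is available by flag and agrees to high precision on clean data. A fitted
rate ≤ 0 is reported with `half_life = Inf` and a `nondecaying` flag rather
than as an error: stable proteins are a legitimate outcome. Published
remaining fractions are typically rounded to two digits, so worked examples
are asserted as intervals (e.g. the fast-turnover mutant's fractions
0.70/0.50/0.32 at 8/18/24 h give a half-life of ~15.7 h, within a few
percent of the published 15.5 h), not as exact points.

## What the synthetic generators emulate — and what they do not

Each generator returns its hidden truth alongside the data, so tests check
the analysis against the truth instead of re-deriving it from coordinates.

* `gen_toy_complex()` — two parallel poly-alanine-like chains (backbone N,
  H, CA, C, O; correct bonds) 8 Å apart, residues numbered continuously so
  every residue number is unique. The backbone geometry is schematic but
  bond-inference-consistent: the heavy–heavy < 1.9 Å / X–H < 1.2 Å distance
  heuristic reproduces exactly the constructed bonds.
* `gen_hbond_trajectory()` — each planted donor/acceptor pair follows a
  two-state Markov chain; bonded frames are realized at D–A 2.9 Å and a
  collinear 180° angle, broken frames at 6 Å, both far from the 3.0 Å/135°
  cutoffs so boundary effects can never flip a planted state. Defaults
  plant stationary occupancy 0.70 over 10,000 frames with transition rates
  p_on = 0.56, p_off = 0.24; the lag-1 autocorrelation of 0.2 keeps
  correlated kinetics while giving the 10,000-frame occupancy estimator a
  standard error of ~0.6 points, consistent with the ±2-point recovery
  band the validation uses.
* `gen_interface_trajectory()` — independent Bernoulli contact indicators
  per frame for five residue pairs at WT probabilities 0.9/0.8/0.5/0.3/0.1
  and mutant probabilities scaled by a contact ratio of 0.66 (an expected
  34% overall reduction), on identical topology and numbering.
* `gen_mode_trajectory()` — frames are `base + a_t·mode + noise`, with
  Gaussian or two-component-mixture amplitudes (the mixture reproduces a
  bimodal PC1 with a dominant peak, e.g. 70/30 at −15/+5 Å). The planted
  mode is projected orthogonal to the 6-dimensional rigid-body subspace
  before use: a random 3N-vector has an O(√(6/3N)) rigid component that
  superposition would silently absorb, and the planted truth is defined as
  a purely internal motion. Defaults: 1 Å amplitude, 0.05 Å noise,
  2,000 frames.
* `gen_rigid_trajectory()` — random rigid transforms of the base plus
  optional isotropic noise, for superposition-invariance checks (expected
  time-averaged RMSD under pure noise of s.d. σ per coordinate is ≈ σ√3).
* `gen_decay_series()` — `exp(−t ln2/t½) · exp(ε)`, ε ~ N(0, σ²)
  (multiplicative band noise), on the chase grid 0/8/18/24 h, σ = 0.02 by
  default.

All generators draw from sub-seeds derived from one master seed and a
per-generator tag (`sub_seed()`), so outputs are bit-reproducible and
adding a generator never perturbs existing fixtures.

These generators emulate the *statistical* structure the analyses assume —
two-state bond kinetics, independent per-pair contacts, one dominant mode
plus isotropic noise, log-normal band noise. They do **not** emulate
force-field physics: no solvent, no thermostat, no coupling between bonds,
no anharmonicity, no periodic-box artifacts. Passing tests therefore
demonstrate that the estimators recover planted truths under their own
model assumptions at realistic sample sizes; they do not certify behaviour
on real trajectories where those assumptions are approximations (e.g.
contact indicators are correlated in real interfaces, and PC1 of a real
protein is rarely this dominant).

## Numerical choices and degenerate inputs

* Coordinates are Å everywhere; atom and frame indices are **1-based**
  (R and bio3d convention); residue numbers follow the source file.
* PDB I/O and DCD reading delegate to `bio3d`; DCD writing is a minimal
  single-precision CHARMM-format writer (round-trip verified against
  `bio3d::read.dcd`). XTC is not supported and raises an informative
  error. PDB round-trips are exact to the format's 1e-3 Å precision;
  DCD to single-precision (~1e-5 relative).
* Chain-id collisions across non-contiguous segments are resolved by
  renaming segments A, B, ... with a warning.
* Coincident donor/acceptor coordinates raise a geometry error rather than
  returning NaN angles; < 3 fit atoms or collinear fit sets raise a
  superposition error; empty measure selections are errors, while empty
  *match* results from a selection expression are legal.
* Ties in the groove ranking are broken by ascending residue number; ties
  at H-bond cutoffs count as bonded.
* The problem sizes used in tests and validation (10,000-frame occupancy
  and contact runs, 2,000-frame PCA runs, 100–500 replicate decay fits,
  10-atom brute-force superposition oracles) were chosen so each planted
  truth is recovered well inside its stated tolerance on a single CPU.

## Known limitations

* Contact enumeration is O(donors × acceptors × frames) in plain R —
  adequate for interface selections (tens of atoms per side, 10⁴ frames),
  not for whole-proteome contact matrices.
* The histogram-intersection divergence depends on bin count at small
  sample sizes; compared systems are always binned jointly, and 100 bins
  is a sensible default for ≥ 10³ frames.
* `read_structure()` infers bonds from first-frame distances when the file
  has no CONECT records; exotic geometries (metal sites, very short
  nonbonded contacts) can over-connect. Donor detection only needs N/O–H
  bonds, which the heuristic handles robustly.
* The turnover model is a single exponential through (0, 1); biphasic
  decay or a stable sub-pool will show up as lack of fit (`rss`), not as a
  second rate.
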