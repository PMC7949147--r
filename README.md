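# mdiface

Comparative molecular-dynamics interface analysis and protein turnover
kinetics for R.

Point mutations in a pseudokinase scaffolding domain can destabilize a
protein–protein complex *allosterically* — without touching the binding
surface — by rewiring internal hydrogen bonds and collective motions.
`mdiface` is for structural bioinformaticians who have MD trajectories of a
wild-type two-chain complex and of one or more mutants and want to quantify
that destabilization, and for cell biologists quantifying the matching
protein-turnover (cycloheximide-chase) experiments.

## What it computes

* **Hydrogen-bond occupancy** — for a donor–H–acceptor triple, the percent
  of frames with d(D, A) ≤ 3.0 Å and ∠(D–H–A) ≥ 135° (configurable, closed
  boundaries), plus composite (sum / union) occupancies for bond groups.
* **Interface contact maps and contact reduction** — per-residue
  intermolecular contact occupancy between two chains and the
  mutant-versus-WT reduction
  `100·(1 − occ_mut/occ_wt)` per residue (zero-WT residues masked) and
  `100·(1 − n̄_mut/n̄_wt)` overall, where n̄ is the mean number of contacting
  atom pairs per frame. Per-residue reductions can be written into the
  B-factor column of a PDB for colorimetric mapping.
* **Subdomain RMSD** — time-averaged RMSD of any selection after optimal
  rigid (Kabsch/SVD) superposition on any other selection.
* **Trajectory PCA** — eigendecomposition of the Cartesian coordinate
  covariance after superposing frames on the iterative mean structure;
  density-normalized PC1 histograms and a histogram-intersection divergence
  `1 − Σ min(ρ_a, ρ_b)·Δx` to compare systems.
* **Turnover kinetics** — loading-control normalization, single-exponential
  fits `f(t) = e^(−kt)` (through-origin log-linear regression,
  `t½ = ln 2 / k`), CHX/vehicle ratios, and the expected offspring fraction
  of a multi-locus cross.
* **Synthetic trajectories with planted truth** — seeded generators for
  two-state Markov H-bonds, Bernoulli interface contacts with a planted
  mutant/WT ratio, one planted collective mode, rigid-body motion, and
  noisy decay series, so every analysis stage is validated against known
  ground truth.

Formats: PDB (read/write, multi-model), DCD (read/write). The comparison
pipeline (`run_compare()`) takes a config (R list or YAML), emits TSV/JSON
reports plus B-factor PDBs, and writes a manifest with MD5 checksums;
identical config and seed give byte-identical outputs.

## Worked example

Plant a mutant/WT interface contact ratio of 0.66 across five residue
pairs, recover the overall reduction, and fit the published-style chase
fractions of a fast-turnover mutant:

```r
library(mdiface)

gi <- gen_interface_trajectory(n_frames = 10000, seed = 1)  # ratio 0.66
wt  <- contact_map(gi$wt,     "chain A", "chain B")
mut <- contact_map(gi$mutant, "chain A", "chain B")
reduction_profile(wt, mut)
#> reduction profile: overall 34.4%, 5 residues (0 masked)

fit_decay(decay_series(c(0, 8, 18, 24), c(1, 0.70, 0.50, 0.32)))
#> decay fit (loglinear): k = 0.04427 /h, half-life = 15.66 h, rss = 0.003085

cross_probability(c(0.5, 0.5, 0.5))   # mutant allele x floxed allele x Cre
#> [1] 12.5
```

The overall reduction lands within sampling error of the planted 34%; the
chase fractions (remaining protein 70%/50%/32% at 8/18/24 h) give a
half-life of 15.7 h.

## Analysis workflow

`analysis/` contains numbered drivers that run the full study on the
synthetic set and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R           # build the seeded study set
Rscript analysis/02_hbond_occupancy.R    # occupancy + composite occupancies
Rscript analysis/03_interface_contacts.R # contact maps, reduction, groove
Rscript analysis/04_rmsd_pca.R           # subdomain RMSD, PCA, PC1 histograms
Rscript analysis/05_turnover.R           # chase fits, ratios, cross odds
```

Representative output: occupancy 69.90% against a hidden-state truth of
69.90% (planted stationary 0.70); overall contact reduction 34.4% (planted
34.0%); PC1 aligned with the planted mode at |cos| = 0.9998; time-averaged
RMSD 9e-15 Å for pure rigid motion and 0.172 Å for 0.1-Å noise
(σ√3 = 0.173 Å).

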