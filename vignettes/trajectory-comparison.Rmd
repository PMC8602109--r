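---
title: "Comparing MD conformational ensembles with trajan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing MD conformational ensembles with trajan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajan)
```

## The problem trajan addresses

Allosteric activators of multi-subunit enzymes — the motivating system is
AMP-activated protein kinase (AMPK), whose α-kinase domain and β-subunit
carbohydrate-binding module (CBM) sandwich a drug site at their interface —
change *dynamics* more than they change average structure. Deciding whether
an activator rigidifies a complex, re-routes inter-subunit communication, or
pre-organizes the ATP site therefore requires comparing whole conformational
ensembles (apo vs activator-bound "holo" vs holo+ATP, each typically in
several independent replicas), not single structures. trajan packages the
standard comparative toolbox for this design:

* per-frame backbone **RMSD** against a window-averaged reference, and
  per-residue **RMSF** averaged across replicas;
* **essential dynamics** (ED): eigendecomposition of the 3N × 3N positional
  covariance of a selection, per-mode variance fractions, and the **RMSIP**
  similarity between the leading subspaces of two replicas or windows;
* **dynamic cross-correlation** (DCC): `C_ij = <Δr_i·Δr_j> /
  (<Δr_i²><Δr_j²>)^{1/2}` over one representative (Cα) atom per residue,
  with the continuous **Tanimoto** index `x·y/(x·x + y·y − x·y)` for
  comparing matrices;
* **dynamical perturbation networks** (DPN): residue graphs weighted by the
  time- and replica-averaged number of heavy-atom pairs closer than 5 Å,
  subtracted between states, thresholded (default 5) and pruned;
* **communication paths** (WISP-style): shortest and near-shortest simple
  paths on a residue graph with edge weights `w_ij = −log|C_ij|`;
* **conformational clustering**: K-means under the pairwise superposed
  coordinate-RMSD metric with sieved initialization;
* **binding-site statistics**: site-restricted RMSD distributions with peak
  detection and overlap fractions, group-minimum distance series for salt
  bridges/H-bonds, and two-partner orientation occupancies.

## The synthetic-data module is first-class

Published MD trajectories are rarely deposited, so trajan validates every
stage against generated ensembles whose statistical structure is known
exactly rather than against irreproducible reference numbers. The generator
(`gaussian_ensemble_spec()`, `make_gaussian_ensemble()`) samples

    frame_t = reference + Σ_k sqrt(λ_k) z_tk v_k + ε_t,

with orthonormal 3N direction fields `v_k`, variances `λ_k` (Å²), and
isotropic Gaussian noise of SD σ. Its covariance is exactly
`Σ_k λ_k v_k v_kᵀ + σ² I`, which makes the DCC matrix (`analytic_dcc()`),
the ED spectrum and the per-coordinate variances available in closed form.
Two further generators plant discrete structure: `make_two_state_pair()`
rigidly displaces a residue block in one state (ground truth for
perturbation networks, via `contact_ground_truth()`), and
`make_conformer_mixture()` draws frames from weighted conformers (ground
truth for clustering). All generators are pure functions of
`(spec, n_frames, seed)`.

What the generator *does not* emulate: force-field energetics, solvent,
anharmonicity, kinetics, and the slow conformational relaxation that makes
real replica comparisons interesting. A green planted-recovery test
establishes that an analysis recovers the statistical feature it claims to
measure at the stated sampling depth — not that the feature is present in
any particular protein.

### Default miniature system

Residues are modelled with 3 pseudo-atoms (a "CA" plus two side-chain
carbons) so Cα-based analyses (DCC, ED) and heavy-atom analyses (contact
networks, site distances) are exercised on one object; test systems use
10–50 residues split over two chains tagged `alpha`/`beta` (the paper-scale
~370-residue two-subunit layout is supported but not required). Default
generator parameters in the demo study — mode variances 1.0/0.25 Å²,
noise σ = 0.15 Å, a 3.5 Å block displacement for non-apo states, state
amplitude scales 1.0/0.85/0.55 for apo/holo/holo+ATP — were chosen once to
mimic the qualitative picture of a direct-activator study (ligand binding
stiffens the ensemble and rearranges interface contacts) at amplitudes
typical of backbone fluctuations, and are not tuned to any test.

## Numerical choices and conventions

* **Superposition** is a least-squares rigid-body fit (SVD/Kabsch with the
  determinant correction, so reflections never occur). An independent
  quaternion-eigenvalue oracle checks it in the tests.
* **Planted modes vs fitting.** A direction field with a net translation or
  rotation component would be partially removed by superposition, so
  `project_out_rigid_body()` removes the rigid component *as seen by the
  fit atoms* before a mode is planted. Even then, fitting a small system
  against a noisy reference removes six degrees of freedom of the noise and
  perturbs correlations by O(1/N) — a known small-system artifact that
  vanishes at protein scale. Closed-form comparisons in the tests therefore
  run with `fit = FALSE` (the generator emits frames in a common frame, so
  superposition is a statistical no-op there); fitting behaviour is tested
  separately on rigid motions.
* **Windows** are half-open frame-index ranges `[start, end)`, with
  `last_frames()`/`last_ns()` conveniences resolved via the ensemble's
  `frame_stride`; the conventional analysis window is the trailing half of
  a trajectory ("last 500 ns" at paper scale).
* **References.** Published comparisons of this kind use an
  *energy-minimized* average structure as RMSD reference; with no force
  field in scope, trajan uses the plain coordinate average of the stated
  window (`average_structure()`). This is a deliberate, documented
  deviation.
* **"Backbone"** = N, CA, C, O of non-HETATM residues; ligands are retained
  as their own residue and excluded from backbone/Cα selections.
* **Contacts** use strict `< cutoff` (default 5 Å) between heavy atoms;
  same-chain pairs with sequence separation ≤ 1 are excluded from networks
  by default (their covalent contacts are constant and uninformative),
  configurable down to no exclusion — and the pipeline's WISP contact mask
  does keep sequence neighbours, since communication paths legitimately run
  along the backbone. Averaging is frames-first, then equal-weight across
  replicas.
* **DPN threshold** keeps edges with `|Δ| >` threshold (default 5, the
  conventional visualization threshold); isolated nodes are pruned;
  positive sign = gain (red by convention), negative = loss (blue).
* **Tanimoto on matrices** is computed on flattened upper triangles with
  the diagonal excluded: it is identically 1 and would only inflate
  similarity.
* **RMSIP** is used as the ED similarity index (the standard choice in the
  ED literature; the per-mode |dot| matrix is exposed so alternative
  indices can be derived). `k = 3` by default, `k = 1` for the "first
  essential motion" alone.
* **Suboptimal paths** are enumerated exactly (DFS bounded by the Dijkstra
  distance-to-sink), not sampled; ties break lexicographically by node
  sequence. `top_k` mode grows the weight bound geometrically until k paths
  exist, bounded by the total edge weight.
* **Clustering** seeds with k-means++ in RMSD space from the given seed,
  iterates Lloyd updates with superposed-mean centroids on every
  `sieve`-th frame, then assigns remaining frames in a single
  nearest-centroid pass (no further refinement), matching the sieve
  convention of cpptraj-style K-means. Results are deterministic in
  `(data, k, sieve, seed)`. Note that the superposed-RMSD metric is blind
  to rigid motions: conformers that differ only by translation/rotation
  belong to one cluster by construction.
* **Site distributions** use 0.1 Å histogram bins and a Gaussian kernel
  density with Silverman's bandwidth; peaks are local maxima above 5% of
  the density maximum. The "fraction resembling the bound state" is the
  fraction of frames at or below a cutoff placed, by default, at the
  density valley between the first two peaks — the cutoff actually used is
  always reported, because the fraction is meaningless without it.
* **Salt bridges / hydrogen bonds** are summarized as group-minimum
  heavy-atom distances (mean ± population SD and occupancy below a
  cutoff); donor–H–acceptor angles are not used.

## Published-table arithmetic

Two published summary tables from the motivating AMPK/PF-739 study are
bundled as CSV inputs (`reference_rmsd_table()`, `reference_ed_table()`)
and their aggregate columns recomputed
(`recompute_reference_aggregates()`). All six ED totals agree with the
printed totals within 0.1 (one row reflects 65.9 printed as 66.0). Five of
six RMSD replica means agree with the printed average within 0.05; the
α2β1/holo row is internally inconsistent at that tolerance (printed
replicas 2.5/2.6/2.9 average to 2.667 against a printed 2.6), evidently
because the published average was formed from unrounded per-replica
values. The corresponding acceptance assertion is kept at its stated
tolerance and fails honestly on that row.

## Worked example

```{r}
spec <- local({
  st <- synthetic_structure(10)
  ca <- select_atoms(st, "calpha")
  m <- orthonormalize_modes(project_out_rigid_body(
    cbind(plant_mode(st, sin(seq(0, pi, length.out = 10)), c(1, 0, 0))),
    st$reference_coords, ca))
  gaussian_ensemble_spec(st, m, 1.0, noise_sigma = 0.1)
})
e <- make_gaussian_ensemble(spec, 2000, seed = 1)
ed <- compute_ed(e, selection = select_atoms(spec$structure, "calpha"),
                 fit = FALSE)
round(head(ed$variance_fraction, 3), 1)
d <- compute_dcc(e, fit = FALSE)
round(d$matrix[1:3, 1:3], 2)
max(abs(d$matrix - analytic_dcc(spec)$matrix))
```

## End-to-end pipeline

`run_pipeline()` (or the `inst/cli/trajan` front end, subcommands
`simulate-synthetic`, `rmsd`, `rmsf`, `ed`, `dcc`, `dpn`, `wisp`,
`cluster`, `site`, `run-all`) executes the full comparative design —
systems × states × replicas — from a single JSON config, writing CSV/JSON/
GraphML reports plus a manifest (package version, seed, parameters) that
suffices to reproduce every number. Reruns with the same `(config, seed)`
are byte-identical.

## Known limitations

* Trajectory formats: multi-model PDB and DCD only. XTC requires the
  xdrfile compressed-coordinate codec, which is unavailable offline in
  this environment, so it is out of scope; nm-based inputs can be
  normalized via the reader's `scale` argument.
* No periodic-boundary imaging/unwrapping; inputs are assumed whole.
* Suboptimal-path enumeration is exact and therefore exponential in the
  worst case; it is intended for residue graphs at the scale where WISP
  analyses are actually read (tens of nodes, contact-masked).
* The published similarity indices, Tanimoto values, cluster populations
  and distance statistics of the motivating study derive from 18 μs of
  undeposited trajectories; they are emulated *in kind* on synthetic data,
  and no numerical reproduction is claimed beyond the table arithmetic
  above.
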