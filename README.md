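# trajan — comparative analysis of MD trajectory ensembles

trajan is an R package for comparing molecular-dynamics conformational
ensembles of multi-subunit proteins across ligation states and replicas.
The motivating design is a direct-activator study of AMP-activated protein
kinase (AMPK): apo vs activator-bound (holo) vs holo+ATP complexes of an
α-kinase-domain/β-CBM pair, each simulated in independent replicas, where
the scientific questions — does the activator rigidify the complex,
re-route inter-subunit communication, pre-organize the ATP site? — are
questions about ensembles, not single structures.

## What it computes

| Analysis | Core statistic |
|---|---|
| `rmsd_series`, `rmsf_profile` | backbone RMSD vs a window-averaged reference; per-residue RMSF with cross-replica mean ± SD |
| `compute_ed`, `variance_fractions`, `mode_similarity` | essential dynamics: eigendecomposition of the 3N×3N positional covariance; per-mode variance %; RMSIP between leading subspaces |
| `compute_dcc`, `tanimoto_similarity` | dynamic cross-correlation `C_ij = ⟨Δr_i·Δr_j⟩ / (⟨Δr_i²⟩⟨Δr_j²⟩)^½` on Cα atoms; continuous Tanimoto `x·y/(x·x+y·y−x·y)` between matrices |
| `dynamical_contact_network`, `perturbation` | residue contact networks weighted by heavy-atom couples < 5 Å, time/replica averaged; signed thresholded state differences (threshold 5, isolated nodes pruned) |
| `build_graph`, `optimal_path`, `suboptimal_paths` | WISP-style communication paths on edge weights `w_ij = −log|C_ij|`, exact suboptimal enumeration |
| `kmeans_rmsd`, `populations` | K-means under the pairwise superposed coordinate-RMSD metric with sieved initialization (sieve 10) |
| `site_rmsd_distribution`, `overlap_fraction`, `pair_distance_stats`, `orientation_occupancy` | binding-site pre-organization distributions, salt-bridge/H-bond distance statistics, two-partner occupancy splits |

A first-class synthetic-data module (`gaussian_ensemble_spec`,
`make_gaussian_ensemble`, `make_two_state_pair`, `make_conformer_mixture`)
generates ensembles with planted covariance modes, planted contact
rearrangements and planted conformer mixtures, so every stage is validated
against analytically known ground truth. I/O covers PDB (topology and
multi-model trajectories) and DCD; `run_pipeline()` plus the
`inst/cli/trajan` command-line front end orchestrate the full
systems × states × replicas design from one JSON config with byte-identical
reruns.

## Worked example

Plant a single collective mode (variance 1 Å², isotropic noise 0.1 Å) on a
10-residue two-chain miniature, sample 2000 frames, and recover it:

```r
library(trajan)
st  <- synthetic_structure(10)
ca  <- select_atoms(st, "calpha")
m   <- orthonormalize_modes(project_out_rigid_body(
         cbind(plant_mode(st, sin(seq(0, pi, length.out = 10)), c(1, 0, 0))),
         st$reference_coords, ca))
spec <- gaussian_ensemble_spec(st, m, 1.0, noise_sigma = 0.1)
e   <- make_gaussian_ensemble(spec, 2000, seed = 1)

ed <- compute_ed(e, selection = ca, fit = FALSE)
round(head(ed$variance_fraction, 3), 1)
#> [1] 55.7  1.9  1.8

d <- compute_dcc(e, fit = FALSE)
round(d$matrix[1:3, 1:3], 2)
#>       1     2     3
#> 1  1.00  0.48 -0.19
#> 2  0.48  1.00 -0.12
#> 3 -0.19 -0.12  1.00

max(abs(d$matrix - analytic_dcc(spec)$matrix))
#> [1] 0.0288
```

The first essential mode carries 55.7% of the CA positional variance (the
planted mode against the isotropic noise floor), the sampled DCC matrix
shows the mode's sign structure, and it agrees with the closed-form DCC of
the generating model to < 0.03 at this sampling depth.

Run the bundled demo study (2 systems × 3 states × 2 replicas, ~3 s):

```sh
Rscript inst/cli/trajan run-all --out demo_out --seed 1
```

which writes Table-style CSVs (RMSD, ED variance fractions, RMSIP, DCC
Tanimoto), DPN edge lists/GraphML, WISP path reports, cluster populations,
site pre-organization summaries, and a run manifest.

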