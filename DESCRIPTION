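Package: trajan
Title: Comparative Analysis of Molecular Dynamics Trajectory Ensembles
Version: 0.1.0
Authors@R:
    person("trajan", "developers", email = "trajan@example.org", role = c("aut", "cre"))
Description: Tools for comparing molecular dynamics (MD) conformational
    ensembles of multi-subunit proteins across ligation states and replicas:
    dynamic cross-correlation matrices with Tanimoto similarity, dynamical
    perturbation contact networks, correlation-weighted suboptimal
    communication paths (WISP-style), essential dynamics with cross-replica
    RMSIP similarity, K-means conformational clustering under a coordinate-RMSD
    metric with sieved initialization, and binding-site pre-organization and
    interaction-geometry statistics. Includes a synthetic-ensemble generator
    with planted covariance modes, two-state contact rearrangements and
    conformer mixtures so that every analysis stage can be validated against
    known ground truth, plus multi-model PDB and DCD trajectory I/O and a
    config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
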