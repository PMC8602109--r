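# Synthetic ensembles with analytically known structure: planted Gaussian
# covariance modes, two-state contact rearrangements, conformer mixtures.
# These stand in for MD trajectories; they have no force field and no
# thermodynamic realism -- only the statistical features the analyses probe.

# run code with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.flat <- function(m) as.vector(t(m))          # (x1,y1,z1,x2,...)
.unflat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Build a miniature two-chain structure
#'
#' Residues are modelled with a small number of pseudo-atoms (default 3: a
#' "CA" plus two side-chain carbons) so that Calpha-based analyses (DCC,
#' essential dynamics) and heavy-atom analyses (contact networks) are both
#' exercised on the same object. Chain A is tagged "alpha", chain B "beta",
#' mirroring a kinase-domain/CBM two-subunit layout.
#'
#' @param n_residues total residue count (split between the two chains).
#' @param atoms_per_residue pseudo-atoms per residue (1--4).
#' @param chain_sep distance (Angstrom) between the two chain axes.
#' @param n_chain_a residues in chain A (default: half, rounded up).
#' @return a `StructureModel` with `reference_coords` set.
#' @export
synthetic_structure <- function(n_residues, atoms_per_residue = 3L,
                                chain_sep = 4.5, n_chain_a = NULL) {
  stopifnot(n_residues >= 2L, atoms_per_residue >= 1L, atoms_per_residue <= 4L)
  if (is.null(n_chain_a)) n_chain_a <- ceiling(n_residues / 2)
  stopifnot(n_chain_a >= 1L, n_chain_a < n_residues)
  anames <- c("CA", "CB", "CG", "CD")[seq_len(atoms_per_residue)]
  rows <- list(); coords <- list()
  for (r in seq_len(n_residues)) {
    in_a <- r <= n_chain_a
    k <- if (in_a) r else r - n_chain_a
    base <- c(3.0 * k, 1.2 * (k %% 2) + if (in_a) 0 else chain_sep, 0)
    offs <- rbind(c(0, 0, 0), c(0, 0, 1.5), c(0, 1.2, 2.4), c(1.0, 0, 3.0))
    for (a in seq_len(atoms_per_residue)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = anames[a], resid = k, resname = "GLY",
        chain = if (in_a) "A" else "B", element = "C",
        stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- base + offs[a, ]
    }
  }
  sm <- structure_model(do.call(rbind, rows),
                        subunit_map = c(A = "alpha", B = "beta"))
  sm$reference_coords <- do.call(rbind, coords)
  colnames(sm$reference_coords) <- c("x", "y", "z")
  sm
}

#' Plant a collective mode over residues
#'
#' Builds a unit 3N direction-field in which every atom of residue `r` moves
#' along `direction` with weight `res_weights[r]`. Weights of zero leave the
#' residue untouched by the mode.
#'
#' @param structure a `StructureModel`.
#' @param res_weights numeric vector over global residue indices (length
#'   `n_residues`), or a named vector keyed by residue index.
#' @param direction 3-vector (need not be unit).
#' @return unit numeric vector of length `3 * n_atoms`.
#' @export
plant_mode <- function(structure, res_weights, direction = c(1, 0, 0)) {
  nres <- n_residues(structure)
  w <- numeric(nres)
  if (!is.null(names(res_weights))) {
    w[as.integer(names(res_weights))] <- res_weights
  } else {
    stopifnot(length(res_weights) == nres)
    w <- res_weights
  }
  d <- direction / sqrt(sum(direction^2))
  v <- matrix(0, n_atoms(structure), 3L)
  for (a in seq_len(n_atoms(structure)))
    v[a, ] <- w[structure$atoms$res_index[a]] * d
  fv <- .flat(v)
  nv <- sqrt(sum(fv^2))
  if (nv == 0) stop("mode has zero norm")
  fv / nv
}

#' Project rigid-body motions out of mode vectors
#'
#' A planted mode with a net translation or rotation component would be
#' partially removed by the least-squares superposition every analysis
#' applies; internal modes must live in the orthogonal complement of the six
#' rigid-body motions at the reference geometry. This projects that
#' component out and renormalizes.
#'
#' @param modes matrix with one 3N mode per column (or a single vector).
#' @param reference `n_atoms x 3` reference coordinates.
#' @param fit_atoms atom indices the downstream superposition fits on
#'   (default: all atoms). The rigid component is measured on these atoms
#'   -- exactly what a least-squares fit on that subset would remove -- and
#'   the corresponding global rigid field is subtracted.
#' @return matrix of unit modes orthogonal to the rigid-body motions as
#'   seen by the fit atoms.
#' @export
project_out_rigid_body <- function(modes, reference, fit_atoms = NULL) {
  m <- as.matrix(modes)
  nat <- nrow(reference)
  stopifnot(nrow(m) == 3L * nat)
  if (is.null(fit_atoms)) fit_atoms <- seq_len(nat)
  ctr <- sweep(reference, 2,
               colMeans(reference[fit_atoms, , drop = FALSE]))
  basis <- matrix(0, 3L * nat, 6L)
  for (d in 1:3) basis[, d] <- .flat(matrix(rep(diag(3)[d, ], nat),
                                            nat, 3, byrow = TRUE))
  axes <- diag(3)
  for (d in 1:3) {
    rot <- t(apply(ctr, 1, function(r) c(axes[d, 2] * r[3] - axes[d, 3] * r[2],
                                         axes[d, 3] * r[1] - axes[d, 1] * r[3],
                                         axes[d, 1] * r[2] - axes[d, 2] * r[1])))
    basis[, 3L + d] <- .flat(rot)
  }
  rows <- as.vector(t(outer(fit_atoms, 1:3, function(a, d) 3L * (a - 1L) + d)))
  Bs <- basis[rows, , drop = FALSE]
  for (k in seq_len(ncol(m))) {
    cf <- qr.solve(Bs, m[rows, k])
    v <- m[, k] - basis %*% cf
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("mode ", k, " is purely rigid-body")
    m[, k] <- v / nv
  }
  m
}

#' Orthonormalize a set of mode vectors (modified Gram-Schmidt)
#' @param modes matrix with one mode per column.
#' @return matrix with orthonormal columns.
#' @export
orthonormalize_modes <- function(modes) {
  m <- as.matrix(modes)
  for (k in seq_len(ncol(m))) {
    if (k > 1L)
      for (j in seq_len(k - 1L))
        m[, k] <- m[, k] - sum(m[, k] * m[, j]) * m[, j]
    nv <- sqrt(sum(m[, k]^2))
    if (nv < 1e-12) stop("modes are linearly dependent")
    m[, k] <- m[, k] / nv
  }
  m
}

#' Specify a Gaussian ensemble with planted modes
#'
#' The model is `frame_t = reference + sum_k sqrt(lambda_k) z_tk mode_k +
#' noise`, with `z_tk` independent standard normals and isotropic Gaussian
#' noise of SD `noise_sigma` on every coordinate. Its 3N x 3N covariance is
#' exactly `sum_k lambda_k v_k v_k' + sigma^2 I`, which makes every
#' downstream statistic analytically computable.
#'
#' @param structure `StructureModel` with `reference_coords`.
#' @param modes matrix `3*n_atoms x K`, mutually orthonormal columns; may be
#'   `NULL` for a modes-free (pure noise) spec.
#' @param lambdas mode variances (Angstrom^2), positive, non-increasing.
#' @param noise_sigma isotropic noise SD (Angstrom), >= 0.
#' @return object of class `GaussianEnsembleSpec`.
#' @export
gaussian_ensemble_spec <- function(structure, modes = NULL, lambdas = numeric(0),
                                   noise_sigma = 0) {
  stopifnot(inherits(structure, "StructureModel"),
            !is.null(structure$reference_coords))
  if (is.null(modes)) modes <- matrix(0, 3L * n_atoms(structure), 0L)
  modes <- as.matrix(modes)
  if (nrow(modes) != 3L * n_atoms(structure))
    stop("modes must have 3*n_atoms rows")
  if (ncol(modes) != length(lambdas))
    stop("one lambda per mode required")
  if (length(lambdas)) {
    if (any(lambdas <= 0)) stop("lambdas must be positive")
    if (is.unsorted(rev(lambdas))) stop("lambdas must be non-increasing")
    G <- crossprod(modes)
    if (max(abs(G - diag(ncol(modes)))) > 1e-8)
      stop("mode direction-fields are not mutually orthonormal")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(structure = structure,
                 reference = structure$reference_coords,
                 modes = modes, lambdas = as.numeric(lambdas),
                 noise_sigma = noise_sigma),
            class = "GaussianEnsembleSpec")
}

#' Sample a Gaussian ensemble
#'
#' @param spec a [gaussian_ensemble_spec()].
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed; same `(spec, n_frames, seed)` gives
#'   bit-identical output and the caller's RNG state is left untouched.
#' @inheritParams ensemble
#' @return an `Ensemble`.
#' @export
make_gaussian_ensemble <- function(spec, n_frames, seed,
                                   frame_stride = 1, replica_id = 1L,
                                   state_label = "custom") {
  stopifnot(inherits(spec, "GaussianEnsembleSpec"), n_frames >= 2L)
  nat <- n_atoms(spec$structure)
  K <- length(spec$lambdas)
  X <- .with_seed(seed, {
    Z <- if (K) matrix(rnorm(n_frames * K), n_frames, K) else NULL
    N <- if (spec$noise_sigma > 0)
      matrix(rnorm(n_frames * 3L * nat, sd = spec$noise_sigma),
             n_frames, 3L * nat) else 0
    D <- if (K) Z %*% (t(spec$modes) * sqrt(spec$lambdas)) else 0
    D + N
  })
  ref_flat <- .flat(spec$reference)
  coords <- array(NA_real_, c(n_frames, nat, 3L))
  for (t in seq_len(n_frames)) {
    fl <- ref_flat + (if (is.matrix(X)) X[t, ] else 0)
    coords[t, , ] <- .unflat(fl)
  }
  ensemble(spec$structure, coords, frame_stride = frame_stride,
           replica_id = replica_id, state_label = state_label)
}

#' Closed-form DCC of a Gaussian spec
#'
#' Evaluates the dynamic cross-correlation matrix directly from the model
#' covariance `sum_k lambda_k v_k v_k' + sigma^2 I` restricted to one
#' representative (CA) atom per residue:
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`.
#'
#' @param spec a [gaussian_ensemble_spec()].
#' @return a `DccMatrix` (see [compute_dcc()]).
#' @export
analytic_dcc <- function(spec) {
  stopifnot(inherits(spec, "GaussianEnsembleSpec"))
  st <- spec$structure
  rep_atoms <- .calpha_indices(st)
  res_index <- st$atoms$res_index[rep_atoms]
  n <- length(rep_atoms)
  # rows of V: 3 coordinates of each representative atom, per mode
  inner <- matrix(0, n, n)
  if (length(spec$lambdas)) {
    for (k in seq_along(spec$lambdas)) {
      Vk <- .unflat(spec$modes[, k])[rep_atoms, , drop = FALSE]
      inner <- inner + spec$lambdas[k] * tcrossprod(Vk)
    }
  }
  diag(inner) <- diag(inner) + 3 * spec$noise_sigma^2
  vars <- diag(inner)
  if (any(vars <= 0))
    stop("residue(s) with zero total variance: ",
         paste(res_index[vars <= 0], collapse = ", "))
  C <- inner / sqrt(outer(vars, vars))
  diag(C) <- 1
  new_dcc_matrix(C, res_index, meta = list(source = "analytic"))
}

# ------------------------------------------------ two-state contact pair ----

#' Specify a two-state (apo vs holo style) contact rearrangement
#'
#' State A samples the base Gaussian spec; state B is identical except that
#' a block of residues is rigidly translated, so the contact gains/losses
#' between the states are computable from static geometry.
#'
#' @param base a [gaussian_ensemble_spec()].
#' @param displaced_block global residue indices (non-empty strict subset).
#' @param displacement 3-vector (Angstrom) applied in state B.
#' @return object of class `TwoStateContactSpec`.
#' @export
two_state_contact_spec <- function(base, displaced_block, displacement) {
  stopifnot(inherits(base, "GaussianEnsembleSpec"))
  nres <- n_residues(base$structure)
  displaced_block <- as.integer(displaced_block)
  if (!length(displaced_block) || length(displaced_block) >= nres ||
      any(displaced_block < 1L) || any(displaced_block > nres))
    stop("displaced_block must be a non-empty strict subset of residues")
  stopifnot(length(displacement) == 3L)
  structure(list(base = base, displaced_block = displaced_block,
                 displacement = as.numeric(displacement)),
            class = "TwoStateContactSpec")
}

.displace_block <- function(structure, coords, block, displacement) {
  rows <- structure$atoms$res_index %in% block
  coords[rows, ] <- sweep(coords[rows, , drop = FALSE], 2, displacement, "+")
  coords
}

#' Sample the two states of a contact-rearrangement spec
#'
#' @param spec a [two_state_contact_spec()].
#' @param n_frames frames per state.
#' @param seed integer seed (state B uses `seed + 1`).
#' @return list with `a` and `b` (`Ensemble`s, state labels "A"/"B").
#' @export
make_two_state_pair <- function(spec, n_frames, seed) {
  stopifnot(inherits(spec, "TwoStateContactSpec"))
  a <- make_gaussian_ensemble(spec$base, n_frames, seed, state_label = "A")
  b <- make_gaussian_ensemble(spec$base, n_frames, seed + 1L, state_label = "B")
  st <- spec$base$structure
  for (t in seq_len(n_frames))
    b$coords[t, , ] <- .displace_block(st, get_frame(b, t),
                                       spec$displaced_block, spec$displacement)
  list(a = a, b = b)
}

#' Static contact ground truth for a two-state spec
#'
#' Counts heavy-atom contacts on the noise-free reference geometry of each
#' state and returns the residue pairs whose counts differ -- the planted
#' gains and losses a perturbation network should recover.
#'
#' @param spec a [two_state_contact_spec()].
#' @param cutoff contact cutoff (Angstrom), strict `<`.
#' @param exclude_adjacent drop pairs with `|i - j| <=` this sequence
#'   separation on the same chain (default 1).
#' @return data.frame `i, j, count_a, count_b, delta` (only rows with
#'   `delta != 0`).
#' @export
contact_ground_truth <- function(spec, cutoff = 5.0, exclude_adjacent = 1L) {
  st <- spec$base$structure
  ref_a <- spec$base$reference
  ref_b <- .displace_block(st, ref_a, spec$displaced_block, spec$displacement)
  ca <- contact_counts_frame(ref_a, st, cutoff = cutoff,
                             exclude_adjacent = exclude_adjacent)
  cb <- contact_counts_frame(ref_b, st, cutoff = cutoff,
                             exclude_adjacent = exclude_adjacent)
  key <- function(d) paste(d$i, d$j)
  allk <- union(key(ca), key(cb))
  va <- setNames(ca$count, key(ca))[allk]; va[is.na(va)] <- 0
  vb <- setNames(cb$count, key(cb))[allk]; vb[is.na(vb)] <- 0
  ij <- do.call(rbind, strsplit(allk, " "))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    count_a = as.numeric(va), count_b = as.numeric(vb),
                    delta = as.numeric(vb - va))
  out <- out[out$delta != 0, , drop = FALSE]
  out[order(out$i, out$j), , drop = FALSE]
}

# ------------------------------------------------------ conformer mixture ----

#' Specify a discrete conformer mixture
#'
#' @param structure `StructureModel` shared by all conformers.
#' @param conformers list of `n_atoms x 3` reference coordinate matrices
#'   (>= 2).
#' @param weights sampling probabilities (sum to 1).
#' @param jitter_sigma isotropic Gaussian jitter SD (Angstrom).
#' @return object of class `ConformerMixtureSpec`.
#' @export
conformer_mixture_spec <- function(structure, conformers, weights,
                                   jitter_sigma = 0) {
  stopifnot(inherits(structure, "StructureModel"))
  if (!is.list(conformers) || length(conformers) < 2L)
    stop("need at least 2 conformers")
  for (cf in conformers)
    stopifnot(is.matrix(cf), nrow(cf) == n_atoms(structure), ncol(cf) == 3L)
  if (length(weights) != length(conformers))
    stop("one weight per conformer required")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  structure(list(structure = structure, conformers = conformers,
                 weights = as.numeric(weights),
                 jitter_sigma = jitter_sigma),
            class = "ConformerMixtureSpec")
}

#' Minimum pairwise conformer RMSD of a mixture spec
#'
#' Fixtures are considered cleanly separable when this exceeds about 3x the
#' jitter SD (and clustering recovery is asserted only above 5x).
#'
#' @param spec a [conformer_mixture_spec()].
#' @param fit superpose conformers before measuring (default TRUE).
#' @export
min_pairwise_conformer_rmsd <- function(spec, fit = TRUE) {
  k <- length(spec$conformers)
  best <- Inf
  sel <- seq_len(n_atoms(spec$structure))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    a <- spec$conformers[[i]]; b <- spec$conformers[[j]]
    if (fit) a <- .fit_coords(a, b, sel)
    best <- min(best, .rmsd(a, b))
  }
  best
}

#' Sample a conformer mixture
#'
#' @param spec a [conformer_mixture_spec()].
#' @param n_frames frames to draw (>= number of conformers).
#' @param seed integer seed.
#' @return list with `ensemble` and integer `labels` (ground truth per
#'   frame, 1-based conformer index).
#' @export
make_conformer_mixture <- function(spec, n_frames, seed) {
  stopifnot(inherits(spec, "ConformerMixtureSpec"),
            n_frames >= length(spec$conformers))
  nat <- n_atoms(spec$structure)
  res <- .with_seed(seed, {
    labels <- sample.int(length(spec$conformers), n_frames, replace = TRUE,
                         prob = spec$weights)
    jit <- if (spec$jitter_sigma > 0)
      array(rnorm(n_frames * nat * 3L, sd = spec$jitter_sigma),
            c(n_frames, nat, 3L)) else NULL
    list(labels = labels, jit = jit)
  })
  coords <- array(NA_real_, c(n_frames, nat, 3L))
  for (t in seq_len(n_frames)) {
    fr <- spec$conformers[[res$labels[t]]]
    if (!is.null(res$jit)) fr <- fr + res$jit[t, , ]
    coords[t, , ] <- fr
  }
  list(ensemble = ensemble(spec$structure, coords),
       labels = res$labels)
}
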