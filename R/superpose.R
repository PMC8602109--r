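# Rigid-body superposition (Kabsch), RMSD/RMSF surface.

# Optimal proper rotation R and translation mapping P onto Q (both n x 3):
# argmin_R,t sum ||(P - cP) R - (Q - cQ)||^2, det(R) = +1 always.
.kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3L)
  cP <- colMeans(P); cQ <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cP), sweep(Q, 2, cQ))
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, cP = cP, cQ = cQ)
}

# apply a fit computed on `sel` rows to all rows of `coords`
.fit_coords <- function(coords, ref, sel) {
  k <- .kabsch(coords[sel, , drop = FALSE], ref[sel, , drop = FALSE])
  sweep(sweep(coords, 2, k$cP) %*% k$R, 2, k$cQ, "+")
}

# plain coordinate RMSD between two already-aligned coordinate sets
.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Superpose every frame of an ensemble onto a reference
#'
#' Least-squares rigid-body fit (rotation + translation, never a reflection)
#' computed on the selected atoms and applied to all atoms of each frame.
#'
#' @param x an `Ensemble`.
#' @param reference a frame index into `x`, or an `n_atoms x 3` matrix.
#' @param selection atom indices used for the fit (see [select_atoms()]);
#'   default all atoms.
#' @return the superposed `Ensemble`.
#' @export
superpose <- function(x, reference = 1L, selection = NULL) {
  stopifnot(inherits(x, "Ensemble"))
  ref <- if (is.matrix(reference)) reference else get_frame(x, reference)
  if (is.null(selection)) selection <- seq_len(dim(x$coords)[2])
  if (length(selection) < 3L)
    stop("need at least 3 atoms in the fit selection")
  pts <- ref[selection, , drop = FALSE]
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 2L)
    stop("fit selection is collinear")
  out <- x
  for (t in seq_len(n_frames(x)))
    out$coords[t, , ] <- .fit_coords(get_frame(x, t), ref, selection)
  out
}

#' Per-frame RMSD against a reference
#'
#' Each frame is (by default) rigid-body fitted onto the reference on the
#' given selection, then the RMSD over that selection is computed. The
#' summary mean and population standard deviation are taken over the stated
#' window.
#'
#' @param x an `Ensemble`.
#' @param reference frame index or `n_atoms x 3` matrix.
#' @param selection atom indices (default all).
#' @param window frame window, see [resolve_window()].
#' @param fit superpose each frame before measuring (default `TRUE`).
#' @return object of class `RmsdSeries`: `values` (Angstrom, one per window
#'   frame), `frames`, `mean`, `sd` (population SD).
#' @export
rmsd_series <- function(x, reference = 1L, selection = NULL, window = NULL,
                        fit = TRUE) {
  stopifnot(inherits(x, "Ensemble"))
  ref <- if (is.matrix(reference)) reference else get_frame(x, reference)
  if (is.null(selection)) selection <- seq_len(dim(x$coords)[2])
  idx <- resolve_window(x, window)
  vals <- vapply(idx, function(t) {
    fr <- get_frame(x, t)
    if (fit) fr <- .fit_coords(fr, ref, selection)
    .rmsd(fr[selection, , drop = FALSE], ref[selection, , drop = FALSE])
  }, numeric(1))
  structure(list(values = vals, frames = idx,
                 mean = mean(vals),
                 sd = sqrt(mean((vals - mean(vals))^2)),
                 selection = selection, fit = fit),
            class = "RmsdSeries")
}

#' @export
print.RmsdSeries <- function(x, ...) {
  cat(sprintf("RmsdSeries: %d frames, mean %.2f +/- %.2f Angstrom\n",
              length(x$values), x$mean, x$sd))
  invisible(x)
}

#' Window-average structure
#'
#' Frames of the window are superposed onto the first window frame (on the
#' given selection), then averaged per atom. This plain coordinate average
#' stands in for an energy-minimized average structure.
#'
#' @inheritParams rmsd_series
#' @return `n_atoms x 3` matrix (Angstrom).
#' @export
average_structure <- function(x, window = NULL, selection = NULL, fit = TRUE) {
  idx <- resolve_window(x, window)
  if (!length(idx)) stop("empty window")
  ref <- get_frame(x, idx[1])
  if (is.null(selection)) selection <- seq_len(dim(x$coords)[2])
  acc <- matrix(0, dim(x$coords)[2], 3L)
  for (t in idx) {
    fr <- get_frame(x, t)
    if (fit) fr <- .fit_coords(fr, ref, selection)
    acc <- acc + fr
  }
  acc / length(idx)
}

#' Per-residue RMSF profile across replicas
#'
#' For each replica, frames of the window are superposed (on the given
#' selection) onto the replica's window-average structure, and the
#' root-mean-square fluctuation about that average is computed per residue
#' (averaging squared deviations over the residue's selected atoms). The
#' cross-replica mean and SD give Fig-3-style error bars.
#'
#' @param replicas list of `Ensemble`s sharing one structure.
#' @param selection atom indices whose fluctuations are measured (default
#'   backbone).
#' @param window frame window.
#' @param fit_selection atom indices the superposition is anchored on
#'   (default: same as `selection`; pass the static part of the system to
#'   keep a localized motion from leaking into the frame fit).
#' @return object of class `RmsfProfile`: `res_index`, `per_replica`
#'   (residues x replicas matrix, Angstrom), `mean`, `sd`.
#' @export
rmsf_profile <- function(replicas, selection = NULL, window = NULL,
                         fit_selection = NULL) {
  stopifnot(is.list(replicas), length(replicas) >= 1L)
  st <- replicas[[1]]$structure
  for (r in replicas)
    if (n_atoms(r$structure) != n_atoms(st) ||
        !identical(r$structure$atoms$res_index, st$atoms$res_index))
      stop("replicas have mismatched residue sets")
  if (is.null(selection)) selection <- select_atoms(st, "backbone")
  if (is.null(fit_selection)) fit_selection <- selection
  res_of <- st$atoms$res_index[selection]
  res_levels <- sort(unique(res_of))
  per <- matrix(NA_real_, length(res_levels), length(replicas))
  for (ri in seq_along(replicas)) {
    x <- replicas[[ri]]
    idx <- resolve_window(x, window)
    avg <- average_structure(x, window = idx, selection = fit_selection)
    msd_atom <- numeric(length(selection))
    for (t in idx) {
      fr <- .fit_coords(get_frame(x, t), avg, fit_selection)
      msd_atom <- msd_atom +
        rowSums((fr[selection, , drop = FALSE] -
                 avg[selection, , drop = FALSE])^2)
    }
    msd_atom <- msd_atom / length(idx)
    per[, ri] <- sqrt(vapply(res_levels,
                             function(r) mean(msd_atom[res_of == r]),
                             numeric(1)))
  }
  structure(list(res_index = res_levels, per_replica = per,
                 mean = rowMeans(per),
                 sd = apply(per, 1, function(v)
                   if (length(v) > 1L) stats::sd(v) else 0)),
            class = "RmsfProfile")
}

#' @export
print.RmsfProfile <- function(x, ...) {
  cat(sprintf("RmsfProfile: %d residues, %d replica(s), grand mean %.2f Angstrom\n",
              length(x$res_index), ncol(x$per_replica), mean(x$mean)))
  invisible(x)
}
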