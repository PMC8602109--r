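# Essential dynamics: PCA of the positional covariance of a selection,
# variance contributions per mode, RMSIP similarity between replicas.

#' Essential dynamics of an ensemble
#'
#' Frames of the window are superposed (on the selection) onto the first
#' window frame, the `3N x 3N` positional covariance of the selected atoms
#' is formed about the time mean, and diagonalized. Eigenvectors are the
#' collective deformation modes; eigenvalues their variance contributions.
#'
#' @param x an `Ensemble`.
#' @param selection atom indices (default backbone atoms).
#' @param window frame window.
#' @param fit superpose before analysis (default `TRUE`).
#' @return object of class `EdResult`: `mean_coords` (3N), `eigenvalues`
#'   (Angstrom^2, non-increasing, clipped at 0), `eigenvectors` (3N x 3N,
#'   orthonormal columns), `variance_fraction` (%), `degenerate` flag
#'   (TRUE when the spectrum is numerically zero), `selection`.
#' @export
compute_ed <- function(x, selection = NULL, window = NULL, fit = TRUE) {
  stopifnot(inherits(x, "Ensemble"))
  if (is.null(selection)) selection <- select_atoms(x$structure, "backbone")
  idx <- resolve_window(x, window)
  if (length(idx) < 2L) stop("need at least 2 frames")
  ref <- get_frame(x, idx[1])
  n3 <- 3L * length(selection)
  X <- matrix(NA_real_, length(idx), n3)
  for (k in seq_along(idx)) {
    fr <- get_frame(x, idx[k])
    if (fit) fr <- .fit_coords(fr, ref, selection)
    X[k, ] <- .flat(fr[selection, , drop = FALSE])
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cov <- crossprod(Xc) / (nrow(X) - 1L)
  eg <- eigen(cov, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  degenerate <- sum(ev) < 1e-12
  vf <- if (degenerate) rep(NA_real_, length(ev)) else 100 * ev / sum(ev)
  structure(list(mean_coords = mu, eigenvalues = ev,
                 eigenvectors = eg$vectors, variance_fraction = vf,
                 degenerate = degenerate, selection = selection,
                 total_variance = sum(diag(cov)), n_frames = nrow(X)),
            class = "EdResult")
}

#' @export
print.EdResult <- function(x, ...) {
  cat("EdResult:", length(x$eigenvalues), "modes")
  if (x$degenerate) cat(" (degenerate: zero spectrum)\n")
  else cat(sprintf("; top fractions %%: %s\n",
                   paste(sprintf("%.1f", head(x$variance_fraction, 4)),
                         collapse = ", ")))
  invisible(x)
}

#' Per-mode variance contributions
#'
#' First `k` eigenvalues divided by the trace, as percentages (one decimal
#' is the conventional reporting precision), plus their running `total` --
#' the "contribution of the essential motion" summary of an ED analysis.
#'
#' @param ed an `EdResult`.
#' @param k number of leading modes.
#' @return list `fractions` (length k, %) and `total` (%).
#' @export
variance_fractions <- function(ed, k) {
  stopifnot(inherits(ed, "EdResult"), k >= 1L, k <= length(ed$eigenvalues))
  tr <- sum(ed$eigenvalues)
  if (tr <= 0) stop("zero trace: degenerate spectrum")
  fr <- 100 * ed$eigenvalues[seq_len(k)] / tr
  list(fractions = fr, total = sum(fr))
}

#' RMSIP similarity between two essential-dynamics results
#'
#' Root-mean-square inner product over the first `k` modes:
#' `sqrt( (1/k) sum_{i<=k} sum_{j<=k} (v_i^a . v_j^b)^2 )`, in `[0, 1]`,
#' symmetric and invariant to eigenvector sign flips. The full per-mode
#' `|dot|` matrix is returned so other indices can be derived.
#'
#' @param ed_a,ed_b `EdResult`s over selections of equal dimension.
#' @param k number of leading modes to compare (default 3; use 1 for the
#'   first essential motion alone).
#' @return list `rmsip` (scalar) and `dot_matrix` (k x k, absolute inner
#'   products).
#' @export
mode_similarity <- function(ed_a, ed_b, k = 3L) {
  stopifnot(inherits(ed_a, "EdResult"), inherits(ed_b, "EdResult"))
  if (nrow(ed_a$eigenvectors) != nrow(ed_b$eigenvectors))
    stop("selection dimensions differ")
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= ncol(ed_a$eigenvectors), k <= ncol(ed_b$eigenvectors))
  D <- abs(crossprod(ed_a$eigenvectors[, seq_len(k), drop = FALSE],
                     ed_b$eigenvectors[, seq_len(k), drop = FALSE]))
  list(rmsip = sqrt(sum(D^2) / k), dot_matrix = D)
}

#' Project frames on an essential mode
#'
#' Scalar projection of the mean-centered (superposed) selection coordinates
#' of each window frame on one eigenvector. The projection variance of mode
#' `i` estimates eigenvalue `i`.
#'
#' @param x an `Ensemble`.
#' @param ed the `EdResult` computed from it (same selection).
#' @param mode_index which mode.
#' @param window frame window (default: all frames; projections are taken
#'   about the ED mean, so use the ED window for exact correspondence).
#' @param fit superpose frames as in [compute_ed()].
#' @return numeric vector (Angstrom) of per-frame projections.
#' @export
project_frames <- function(x, ed, mode_index, window = NULL, fit = TRUE) {
  stopifnot(inherits(ed, "EdResult"),
            mode_index >= 1L, mode_index <= ncol(ed$eigenvectors))
  idx <- resolve_window(x, window)
  ref <- get_frame(x, idx[1])
  sel <- ed$selection
  v <- ed$eigenvectors[, mode_index]
  if (ed$eigenvalues[mode_index] <= 0)
    return(numeric(length(idx)))
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    fr <- get_frame(x, idx[k])
    if (fit) fr <- .fit_coords(fr, ref, sel)
    out[k] <- sum((.flat(fr[sel, , drop = FALSE]) - ed$mean_coords) * v)
  }
  out
}

#' Table-2-style CSV report of variance fractions
#'
#' One row per (system, state) with the leading `k` mode percentages and
#' their total.
#'
#' @param results named list: `results[[system]][[state]]` is an `EdResult`.
#' @param k modes to report (default 4).
#' @param path output CSV.
#' @export
write_ed_table <- function(results, path, k = 4L) {
  rows <- list()
  for (sys in names(results)) for (st in names(results[[sys]])) {
    vf <- variance_fractions(results[[sys]][[st]], k)
    rows[[length(rows) + 1L]] <- data.frame(
      system = sys, state = st,
      t(setNames(round(vf$fractions, 1), paste0("proj", seq_len(k)))),
      total = round(vf$total, 1))
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
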