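# Dynamic cross-correlation matrices and Tanimoto similarity.

new_dcc_matrix <- function(C, res_index, meta = list()) {
  dimnames(C) <- list(res_index, res_index)
  structure(list(matrix = C, res_index = as.integer(res_index), meta = meta),
            class = "DccMatrix")
}

#' @export
print.DccMatrix <- function(x, ...) {
  cat("DccMatrix:", length(x$res_index), "residues; off-diagonal range [",
      sprintf("%.3f, %.3f", min(x$matrix[upper.tri(x$matrix)]),
              max(x$matrix[upper.tri(x$matrix)])), "]\n")
  invisible(x)
}

#' Dynamic cross-correlation matrix
#'
#' Computes the per-residue correlation of displacement vectors
#' `C_ij = <dr_i . dr_j> / (<dr_i^2> <dr_j^2>)^(1/2)` with `dr` the
#' displacement of the residue's representative (CA) atom from its time
#' mean, over the stated window. Frames are first least-squares fitted on
#' the CA atoms to the reference (by default the first window frame; the
#' equilibrated starting structure of a simulation is the conventional
#' choice).
#'
#' @param x an `Ensemble`.
#' @param window frame window (see [resolve_window()]).
#' @param fit superpose frames on the CA atoms before correlating
#'   (default `TRUE`).
#' @param reference frame index or `n_atoms x 3` matrix used for fitting.
#' @param res_index optional residue subset.
#' @return object of class `DccMatrix`: symmetric, unit diagonal, entries
#'   in `[-1, 1]`.
#' @export
compute_dcc <- function(x, window = NULL, fit = TRUE, reference = 1L,
                        res_index = NULL) {
  stopifnot(inherits(x, "Ensemble"))
  st <- x$structure
  rep_atoms <- .calpha_indices(st, res_index = res_index)
  resi <- st$atoms$res_index[rep_atoms]
  idx <- resolve_window(x, window)
  ref <- if (is.matrix(reference)) reference else get_frame(x, reference)
  nf <- length(idx); n <- length(rep_atoms)
  # per-coordinate frame matrices of the representative atoms
  if (fit) {
    Xd <- lapply(1:3, function(d) matrix(NA_real_, nf, n))
    for (k in seq_along(idx)) {
      fr <- .fit_coords(get_frame(x, idx[k]), ref, rep_atoms)
      for (d in 1:3) Xd[[d]][k, ] <- fr[rep_atoms, d]
    }
  } else {
    Xd <- lapply(1:3, function(d) {
      m <- x$coords[idx, rep_atoms, d, drop = FALSE]
      dim(m) <- c(nf, n)
      m
    })
  }
  inner <- matrix(0, n, n)
  for (d in 1:3) {
    Xc <- scale(Xd[[d]], center = TRUE, scale = FALSE)
    inner <- inner + crossprod(Xc) / nf
  }
  vars <- diag(inner)
  bad <- vars <= .Machine$double.eps * 100
  if (any(bad))
    stop("residue(s) with zero positional variance: ",
         paste(resi[bad], collapse = ", "))
  C <- inner / sqrt(outer(vars, vars))
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  new_dcc_matrix(C, resi,
                 meta = list(n_frames = nf, fit = fit,
                             state = x$state_label, replica = x$replica_id))
}

#' Continuous Tanimoto similarity between two DCC matrices
#'
#' `T = x.y / (x.x + y.y - x.y)` on the flattened upper triangles
#' (diagonal excluded: it is identically 1 and carries no information).
#' `T(A, A) = 1`; for `B = -A`, `T = -1/3`.
#'
#' @param a,b `DccMatrix` objects over the same residue set.
#' @return scalar similarity (at most 1).
#' @export
tanimoto_similarity <- function(a, b) {
  stopifnot(inherits(a, "DccMatrix"), inherits(b, "DccMatrix"))
  if (!identical(a$res_index, b$res_index))
    stop("DCC matrices are over different residue sets")
  x <- a$matrix[upper.tri(a$matrix)]
  y <- b$matrix[upper.tri(b$matrix)]
  xy <- sum(x * y); xx <- sum(x * x); yy <- sum(y * y)
  if (xx == 0 && yy == 0) stop("both matrices have all-zero off-diagonals")
  xy / (xx + yy - xy)
}

#' Write a DCC matrix as residue-labelled CSV
#' @param x a `DccMatrix`.
#' @param path output file.
#' @export
write_dcc_csv <- function(x, path) {
  df <- as.data.frame(x$matrix)
  names(df) <- paste0("res", x$res_index)
  df <- cbind(res_index = x$res_index, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a DCC matrix written by [write_dcc_csv()]
#' @param path CSV file.
#' @export
read_dcc_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  resi <- as.integer(df$res_index)
  M <- as.matrix(df[, -1, drop = FALSE])
  new_dcc_matrix(unname(M), resi, meta = list(source = path))
}
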