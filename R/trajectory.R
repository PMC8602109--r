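# Ensemble: ordered frames of Cartesian coordinates (Angstrom) for one
# replica of one ligation state, plus trajectory I/O (multi-model PDB, DCD).

#' Create an ensemble
#'
#' @param structure a `StructureModel`.
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom), or a
#'   single `n_atoms x 3` matrix for a one-frame ensemble.
#' @param frame_stride simulated time per frame, in ns (used to resolve
#'   time-based windows such as "last 500 ns").
#' @param replica_id integer replica label.
#' @param state_label one of `"apo"`, `"holo"`, `"holo+ATP"` or any custom
#'   label.
#' @return object of class `Ensemble`.
#' @export
ensemble <- function(structure, coords, frame_stride = 1,
                     replica_id = 1L, state_label = "custom") {
  stopifnot(inherits(structure, "StructureModel"))
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[2] != n_atoms(structure))
    stop("coords atom count (", dim(coords)[2],
         ") does not match structure (", n_atoms(structure), ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  structure(list(structure = structure, coords = coords,
                 frame_stride = frame_stride, replica_id = replica_id,
                 state_label = state_label),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", n_frames(x), "frames x", dim(x$coords)[2], "atoms",
      sprintf("(state=%s, replica=%s)\n", x$state_label, x$replica_id))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x an `Ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' Extract one frame as an n_atoms x 3 matrix
#' @param x an `Ensemble`.
#' @param i frame index.
#' @export
get_frame <- function(x, i) {
  stopifnot(i >= 1, i <= n_frames(x))
  matrix(x$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Resolve a frame window
#'
#' Windows are half-open index ranges `[start, end)` (1-based start, end
#' exclusive), the convenience form `last(k)`, a time window in ns resolved
#' via `frame_stride`, or `NULL` for all frames.
#'
#' @param x an `Ensemble` or a frame count.
#' @param window `NULL`; an integer vector of explicit frame indices
#'   (length != 2); `c(start, end)` half-open; `last_frames(k)`;
#'   or `last_ns(t)`.
#' @return integer vector of frame indices.
#' @export
resolve_window <- function(x, window = NULL) {
  nf <- if (inherits(x, "Ensemble")) n_frames(x) else as.integer(x)
  stride <- if (inherits(x, "Ensemble")) x$frame_stride else 1
  if (is.null(window)) return(seq_len(nf))
  if (inherits(window, "trajan_last_frames")) {
    k <- min(unclass(window), nf)
    return(seq.int(nf - k + 1L, nf))
  }
  if (inherits(window, "trajan_last_ns")) {
    k <- min(max(1L, as.integer(round(unclass(window) / stride))), nf)
    return(seq.int(nf - k + 1L, nf))
  }
  window <- as.integer(window)
  if (length(window) == 2L && window[2] > window[1]) {
    idx <- seq.int(window[1], window[2] - 1L)
  } else {
    idx <- window
  }
  if (!length(idx) || any(idx < 1L) || any(idx > nf))
    stop("window out of range for ", nf, " frames")
  idx
}

#' @rdname resolve_window
#' @param k number of trailing frames.
#' @export
last_frames <- function(k) structure(as.integer(k), class = "trajan_last_frames")

#' @rdname resolve_window
#' @param t trailing simulated time in ns.
#' @export
last_ns <- function(t) structure(as.numeric(t), class = "trajan_last_ns")

#' Subset an ensemble by frames
#' @param x an `Ensemble`; `window` as in [resolve_window()].
#' @param window frame window.
#' @export
subset_frames <- function(x, window) {
  idx <- resolve_window(x, window)
  out <- x
  out$coords <- x$coords[idx, , , drop = FALSE]
  out
}

# ---------------------------------------------------------------- I/O ----

#' Read a trajectory
#'
#' @param structure `StructureModel` whose atom count the file must match.
#' @param path file path.
#' @param format `"pdb"` (multi-model) or `"dcd"`; guessed from the file
#'   extension by default.
#' @param scale multiply coordinates by this factor after reading (use 10 to
#'   normalize nm-based input to Angstrom). Default 1.
#' @inheritParams ensemble
#' @return an `Ensemble` with frames in file order, coordinates in Angstrom.
#' @export
read_trajectory <- function(structure, path, format = c("auto", "pdb", "dcd"),
                            scale = 1, frame_stride = 1, replica_id = 1L,
                            state_label = "custom") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  coords <- switch(format,
                   pdb = .read_pdb_frames(path),
                   dcd = .read_dcd_frames(path))
  if (dim(coords)[2] != n_atoms(structure))
    stop("trajectory atom count (", dim(coords)[2],
         ") does not match structure (", n_atoms(structure), ")")
  if (scale != 1) coords <- coords * scale
  ensemble(structure, coords, frame_stride = frame_stride,
           replica_id = replica_id, state_label = state_label)
}

#' Write a trajectory
#'
#' @param x an `Ensemble`.
#' @param path output file.
#' @param format `"pdb"` (multi-model) or `"dcd"`; guessed from extension.
#' @export
write_trajectory <- function(x, path, format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  switch(format,
         pdb = .write_pdb_frames(x, path),
         dcd = .write_dcd_frames(x, path))
  invisible(path)
}

.read_pdb_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    rec <- lines[is_atom]
    frames <- list(rec)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("truncated multi-model PDB: MODEL/ENDMDL mismatch in ", path)
    frames <- mapply(function(a, b) lines[seq.int(a, b)][is_atom[seq.int(a, b)]],
                     model_starts, model_ends, SIMPLIFY = FALSE)
  }
  nat <- lengths(frames)
  if (!length(frames) || nat[1] == 0L) stop("no coordinates in ", path)
  if (length(unique(nat)) != 1L)
    stop("models differ in atom count in ", path)
  coords <- array(NA_real_, c(length(frames), nat[1], 3L))
  for (t in seq_along(frames)) {
    rec <- frames[[t]]
    coords[t, , 1] <- as.numeric(substr(rec, 31, 38))
    coords[t, , 2] <- as.numeric(substr(rec, 39, 46))
    coords[t, , 3] <- as.numeric(substr(rec, 47, 54))
  }
  if (!all(is.finite(coords))) stop("unparseable coordinates in ", path)
  coords
}

.write_pdb_frames <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL     %4d", t), con)
    writeLines(.format_pdb_atoms(x$structure, get_frame(x, t)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

# Minimal CHARMM-style DCD (no unit cell), single-precision coordinates.
.write_dcd_frames <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(x); nat <- dim(x$coords)[2]
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L  # CHARMM version stamp
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  title <- formatC("Written by trajan", width = 80, flag = "-")
  writeBin(4L + 80L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(4L + 80L, con, size = 4)
  writeBin(4L, con, size = 4); writeBin(nat, con, size = 4)
  writeBin(4L, con, size = 4)
  for (t in seq_len(nf)) {
    for (d in 1:3) {
      writeBin(4L * nat, con, size = 4)
      writeBin(as.numeric(x$coords[t, , d]), con, size = 4)
      writeBin(4L * nat, con, size = 4)
    }
  }
}

.read_dcd_frames <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rec <- function() readBin(con, "integer", 1, size = 4)
  if (rec() != 84L) stop("not a DCD file (bad header record): ", path)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a coordinate DCD: ", path)
  icntrl <- readBin(con, "integer", 20, size = 4)
  rec()
  tlen <- rec()
  readBin(con, "raw", tlen)
  rec()
  rec(); nat <- rec(); rec()
  frames <- list()
  repeat {
    lead <- readBin(con, "integer", 1, size = 4)
    if (!length(lead)) break
    if (lead != 4L * nat) stop("truncated DCD frame in ", path)
    fr <- matrix(NA_real_, nat, 3)
    fr[, 1] <- readBin(con, "numeric", nat, size = 4); rec()
    for (d in 2:3) {
      if (rec() != 4L * nat) stop("truncated DCD frame in ", path)
      fr[, d] <- readBin(con, "numeric", nat, size = 4); rec()
    }
    frames[[length(frames) + 1L]] <- fr
  }
  if (!length(frames)) stop("no frames in ", path)
  coords <- array(NA_real_, c(length(frames), nat, 3L))
  for (t in seq_along(frames)) coords[t, , ] <- frames[[t]]
  coords
}
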