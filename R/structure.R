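# StructureModel: atoms grouped into residues with chain/subunit labels.
# The residue table is the node universe for every network stage.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06)

#' Create a structure model
#'
#' A `StructureModel` is the topology object shared by all analyses: a table
#' of atoms grouped into residues, each residue carrying a chain identifier
#' and (optionally) a subunit tag such as `"alpha"` or `"beta"`.
#'
#' @param atoms data.frame with columns `name` (atom name, e.g. `"CA"`),
#'   `resid` (residue number within its chain), `resname`, `chain`
#'   (single-letter chain id), and optionally `element`, `serial`, `is_het`.
#'   Missing elements are inferred from the first letter of the atom name.
#' @param subunit_map named character vector mapping chain ids to subunit
#'   tags, e.g. `c(A = "alpha", B = "beta")`. Unmapped chains keep their
#'   chain id as tag.
#'
#' @return An object of class `StructureModel` with components `atoms`
#'   (per-atom table including `mass`, `is_heavy` and the global residue
#'   index `res_index`) and `residues` (one row per residue: `res_index`,
#'   `resid`, `resname`, `chain`, `subunit`).
#' @export
structure_model <- function(atoms, subunit_map = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  need <- c("name", "resid", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms$name <- trimws(as.character(atoms$name))
  atoms$resname <- trimws(as.character(atoms$resname))
  atoms$chain <- as.character(atoms$chain)
  if (is.null(atoms$element) || all(is.na(atoms$element))) {
    atoms$element <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atoms$name)
  }
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serial numbers")
  if (is.null(atoms$is_het)) atoms$is_het <- FALSE
  atoms$mass <- unname(.element_masses[atoms$element])
  atoms$mass[is.na(atoms$mass)] <- 12.011
  atoms$is_heavy <- atoms$element != "H"

  key <- paste(atoms$chain, atoms$resid, sep = ":")
  # residues numbered in order of first appearance (file order)
  atoms$res_index <- match(key, unique(key))
  first <- !duplicated(atoms$res_index)
  residues <- data.frame(
    res_index = atoms$res_index[first],
    resid     = atoms$resid[first],
    resname   = atoms$resname[first],
    chain     = atoms$chain[first],
    is_het    = atoms$is_het[first],
    stringsAsFactors = FALSE
  )
  residues$subunit <- residues$chain
  if (!is.null(subunit_map)) {
    hit <- residues$chain %in% names(subunit_map)
    residues$subunit[hit] <- unname(subunit_map[residues$chain[hit]])
  }
  structure(list(atoms = atoms, residues = residues,
                 subunit_map = subunit_map),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues,",
      length(unique(x$residues$chain)), "chain(s)\n")
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)
n_residues <- function(structure) nrow(structure$residues)

.backbone_names <- c("N", "CA", "C", "O")

#' Resolve an atom selection
#'
#' Selections are resolved against a `StructureModel` into a duplicate-free,
#' ordered vector of atom indices. The atom-name classes follow the usual MD
#' conventions: `"backbone"` is N, CA, C, O of non-HETATM residues,
#' `"calpha"` is one CA per residue, `"heavy"` excludes hydrogens.
#'
#' @param structure a `StructureModel`.
#' @param atoms one of `"all"`, `"backbone"`, `"calpha"`, `"heavy"`, or a
#'   character vector of atom names.
#' @param chain optional chain id(s) to restrict to.
#' @param resid optional residue numbers (within chain numbering).
#' @param res_index optional global residue indices.
#' @param include_het include HETATM (ligand) residues; default `FALSE` for
#'   the named classes `"backbone"`/`"calpha"`, `TRUE` otherwise.
#'
#' @return integer vector of atom indices (1-based rows of
#'   `structure$atoms`); errors if the selection is empty.
#' @export
select_atoms <- function(structure, atoms = "all", chain = NULL,
                         resid = NULL, res_index = NULL,
                         include_het = NULL) {
  stopifnot(inherits(structure, "StructureModel"))
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (length(atoms) == 1L && atoms %in% c("all", "backbone", "calpha", "heavy")) {
    if (is.null(include_het)) include_het <- !(atoms %in% c("backbone", "calpha"))
    keep <- switch(atoms,
      all      = keep,
      heavy    = at$is_heavy,
      backbone = at$name %in% .backbone_names,
      calpha   = at$name == "CA")
  } else {
    if (is.null(include_het)) include_het <- TRUE
    keep <- at$name %in% atoms
  }
  if (!include_het) keep <- keep & !at$is_het
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(res_index)) keep <- keep & at$res_index %in% res_index
  idx <- which(keep)
  if (!length(idx))
    stop("selection resolves to zero atoms")
  idx
}

# one representative (CA) atom per residue, in residue order
.calpha_indices <- function(structure, res_index = NULL) {
  idx <- select_atoms(structure, "calpha", res_index = res_index)
  ri <- structure$atoms$res_index[idx]
  if (anyDuplicated(ri)) idx <- idx[!duplicated(ri)]
  idx[order(ri[!duplicated(ri)])]
}

#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records of the first MODEL (or the whole file when no
#' MODEL records are present). Hydrogens are flagged non-heavy; HETATM
#' residues are retained under their own residue and flagged `is_het`.
#'
#' @param path path to a PDB file.
#' @inheritParams structure_model
#' @return a [structure_model()].
#' @export
read_structure <- function(path, subunit_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  end1 <- grep("^ENDMDL", lines)
  if (length(end1)) lines <- lines[seq_len(end1[1] - 1L)]
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  f <- function(a, b) trimws(substr(rec, a, b))
  xs <- suppressWarnings(as.numeric(f(31, 38)))
  ys <- suppressWarnings(as.numeric(f(39, 46)))
  zs <- suppressWarnings(as.numeric(f(47, 54)))
  if (anyNA(xs) || anyNA(ys) || anyNA(zs))
    stop("missing or unparseable coordinates in ", path)
  elem <- f(77, 78)
  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(f(7, 11))),
    name    = f(13, 16),
    resname = f(18, 20),
    chain   = substr(rec, 22, 22),
    resid   = as.integer(f(23, 26)),
    element = ifelse(elem == "", NA_character_, elem),
    is_het  = grepl("^HETATM", rec),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (anyDuplicated(atoms$serial)) stop("duplicate atom ids in ", path)
  sm <- structure_model(atoms, subunit_map = subunit_map)
  sm$reference_coords <- cbind(x = xs, y = ys, z = zs)
  sm
}

.format_pdb_atoms <- function(structure, coords) {
  at <- structure$atoms
  rectype <- ifelse(at$is_het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                  sprintf("%-4s", at$name))
  sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, at$serial %% 100000L, name4, at$resname, at$chain,
          at$resid %% 10000L, coords[, 1], coords[, 2], coords[, 3],
          1, 0, at$element)
}

#' Write a structure (single set of coordinates) as PDB
#'
#' @param structure a `StructureModel`.
#' @param coords n_atoms x 3 matrix of coordinates (Angstrom); defaults to
#'   the structure's stored reference coordinates.
#' @param path output file.
#' @export
write_structure <- function(structure, path, coords = structure$reference_coords) {
  stopifnot(!is.null(coords), nrow(coords) == n_atoms(structure))
  writeLines(c(.format_pdb_atoms(structure, coords), "END"), path)
  invisible(path)
}
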