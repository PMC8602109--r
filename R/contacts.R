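# Dynamical weighted contact networks and signed perturbation networks.
# Contact condition: a heavy atom of residue i strictly closer than the
# cutoff (default 5 Angstrom) to a heavy atom of residue j; the edge weight
# is the number of such atomic couples, time- then replica-averaged.

#' Residue-pair heavy-atom contact counts for one frame
#'
#' @param coords `n_atoms x 3` matrix (Angstrom).
#' @param structure the matching `StructureModel` (heavy atoms flagged).
#' @param cutoff contact distance (Angstrom); strict `<`. Default 5.
#' @param exclude_adjacent drop same-chain pairs with sequence separation
#'   `|i - j| <=` this value (default 1: bonded neighbours carry constant,
#'   uninformative contacts). Use 0 to keep all non-identical pairs.
#' @return data.frame `i, j, count` (global residue indices, `i < j`,
#'   only nonzero counts).
#' @export
contact_counts_frame <- function(coords, structure, cutoff = 5.0,
                                 exclude_adjacent = 1L) {
  stopifnot(nrow(coords) == n_atoms(structure))
  heavy <- which(structure$atoms$is_heavy)
  res <- structure$atoms$res_index[heavy]
  seqno <- structure$atoms$resid[heavy]   # author numbering: sequence gaps count
  chain <- structure$atoms$chain[heavy]
  xyz <- coords[heavy, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  if (nrow(hit)) {
    ri <- res[hit[, 1]]; rj <- res[hit[, 2]]
    si <- seqno[hit[, 1]]; sj <- seqno[hit[, 2]]
    ci <- chain[hit[, 1]]; cj <- chain[hit[, 2]]
    keep <- ri != rj & !(ci == cj & abs(si - sj) <= exclude_adjacent)
    ri <- ri[keep]; rj <- rj[keep]
    if (length(ri)) {
      lo <- pmin(ri, rj); hi <- pmax(ri, rj)
      tab <- table(paste(lo, hi))
      ij <- do.call(rbind, strsplit(names(tab), " "))
      out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                        count = as.numeric(tab))
      return(out[order(out$i, out$j), , drop = FALSE])
    }
  }
  data.frame(i = integer(0), j = integer(0), count = numeric(0))
}

new_contact_network <- function(edges, n_res, meta = list()) {
  structure(list(edges = edges, n_residues = n_res, meta = meta),
            class = "ContactNetwork")
}

#' @export
print.ContactNetwork <- function(x, ...) {
  cat("ContactNetwork:", nrow(x$edges), "edges over",
      x$n_residues, "residues\n")
  invisible(x)
}

# sum sparse edge tables; values combined with `f`
.merge_edges <- function(tables, f = `+`) {
  key <- unlist(lapply(tables, function(d) paste(d$i, d$j)))
  allk <- unique(key)
  acc <- setNames(numeric(length(allk)), allk)
  for (d in tables) {
    k <- paste(d$i, d$j)
    acc[k] <- f(acc[k], d[[3]])
  }
  ij <- do.call(rbind, strsplit(allk, " "))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    value = unname(acc))
  out[order(out$i, out$j), , drop = FALSE]
}

# candidate heavy-atom pairs (upper triangle, residue-filtered) for a
# structure; computed once per network build
.contact_pairs <- function(structure, exclude_adjacent) {
  heavy <- which(structure$atoms$is_heavy)
  res <- structure$atoms$res_index[heavy]
  seqno <- structure$atoms$resid[heavy]
  chain <- structure$atoms$chain[heavy]
  nh <- length(heavy)
  pr <- which(upper.tri(matrix(0, nh, nh)), arr.ind = TRUE)
  ri <- res[pr[, 1]]; rj <- res[pr[, 2]]
  si <- seqno[pr[, 1]]; sj <- seqno[pr[, 2]]
  ci <- chain[pr[, 1]]; cj <- chain[pr[, 2]]
  keep <- ri != rj & !(ci == cj & abs(si - sj) <= exclude_adjacent)
  list(a = heavy[pr[keep, 1]], b = heavy[pr[keep, 2]],
       key = paste(pmin(ri, rj)[keep], pmax(ri, rj)[keep]))
}

# frames x pair contact indicator summed into per-residue-pair mean counts
.mean_counts_ensemble <- function(x, idx, cutoff, exclude_adjacent) {
  p <- .contact_pairs(x$structure, exclude_adjacent)
  if (!length(p$a))
    return(data.frame(i = integer(0), j = integer(0), value = numeric(0)))
  d2 <- matrix(0, length(idx), length(p$a))
  for (d in 1:3) {
    dd <- x$coords[idx, p$a, d, drop = FALSE] -
          x$coords[idx, p$b, d, drop = FALSE]
    dim(dd) <- c(length(idx), length(p$a))
    d2 <- d2 + dd^2
  }
  hits <- colMeans(d2 < cutoff^2)
  agg <- rowsum(hits, p$key)
  ij <- do.call(rbind, strsplit(rownames(agg), " "))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    value = as.numeric(agg))
  out <- out[out$value > 0, , drop = FALSE]
  out[order(out$i, out$j), , drop = FALSE]
}

#' Dynamical weighted contact network
#'
#' Per-frame contact counts are averaged over the window frames of each
#' replica, then averaged across replicas with equal weight.
#'
#' @param replicas one `Ensemble` or a list of them (same structure).
#' @param cutoff contact cutoff (Angstrom), strict `<`; default 5.
#' @param window frame window applied to every replica.
#' @inheritParams contact_counts_frame
#' @return a `ContactNetwork` with `edges` data.frame `i, j, weight`.
#' @export
dynamical_contact_network <- function(replicas, cutoff = 5.0, window = NULL,
                                      exclude_adjacent = 1L) {
  if (inherits(replicas, "Ensemble")) replicas <- list(replicas)
  stopifnot(length(replicas) >= 1L)
  st <- replicas[[1]]$structure
  per_rep <- lapply(replicas, function(x) {
    idx <- resolve_window(x, window)
    if (!length(idx)) stop("empty window")
    .mean_counts_ensemble(x, idx, cutoff, exclude_adjacent)
  })
  avg <- .merge_edges(per_rep)
  avg$value <- avg$value / length(replicas)
  names(avg)[3] <- "weight"
  new_contact_network(avg, n_residues(st),
                      meta = list(cutoff = cutoff,
                                  exclude_adjacent = exclude_adjacent,
                                  n_replicas = length(replicas)))
}

#' Signed perturbation network between two states
#'
#' Edge-wise difference `b - a` of two dynamical contact networks over the
#' same residue universe. Edges with `|delta| <= threshold` are dropped
#' (default threshold 5, the conventional visualization threshold); nodes
#' left without edges are pruned. Positive sign = contact gain in `b`
#' (drawn red by convention), negative = loss (blue).
#'
#' @param net_a,net_b `ContactNetwork`s (same residue count).
#' @param threshold keep edges with `|delta| >` this value; default 5.
#' @return object of class `PerturbationNetwork`: `edges` data.frame
#'   `i, j, delta, sign` ("gain"/"loss"), `nodes` (retained residues).
#' @export
perturbation <- function(net_a, net_b, threshold = 5) {
  stopifnot(inherits(net_a, "ContactNetwork"),
            inherits(net_b, "ContactNetwork"))
  if (net_a$n_residues != net_b$n_residues)
    stop("contact networks are over different residue universes")
  neg <- net_a$edges; if (nrow(neg)) neg$weight <- -neg$weight
  d <- .merge_edges(list(neg, net_b$edges))
  names(d)[3] <- "delta"
  d <- d[abs(d$delta) > threshold, , drop = FALSE]
  d$sign <- ifelse(d$delta > 0, "gain", "loss")
  structure(list(edges = d, nodes = sort(unique(c(d$i, d$j))),
                 threshold = threshold, n_residues = net_a$n_residues),
            class = "PerturbationNetwork")
}

#' @export
print.PerturbationNetwork <- function(x, ...) {
  cat("PerturbationNetwork:", nrow(x$edges), "edges (",
      sum(x$edges$sign == "gain"), "gains,", sum(x$edges$sign == "loss"),
      "losses ) over", length(x$nodes), "nodes; threshold", x$threshold, "\n")
  invisible(x)
}

#' Convert a contact or perturbation network to igraph
#'
#' Node attributes carry chain/subunit tags (and any `region` tags present
#' in the structure's residue table) for downstream coloring.
#'
#' @param x a `ContactNetwork` or `PerturbationNetwork`.
#' @param structure optional `StructureModel` supplying node attributes.
#' @return an `igraph` graph (undirected, weighted).
#' @export
as_igraph <- function(x, structure = NULL) {
  ed <- x$edges
  wcol <- if ("weight" %in% names(ed)) "weight" else "delta"
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$i), to = as.character(ed$j),
               weight = ed[[wcol]],
               sign = if ("sign" %in% names(ed)) ed$sign else "contact"),
    directed = FALSE)
  if (!is.null(structure)) {
    ridx <- as.integer(igraph::V(g)$name)
    rt <- structure$residues
    m <- match(ridx, rt$res_index)
    igraph::V(g)$chain <- rt$chain[m]
    igraph::V(g)$subunit <- rt$subunit[m]
    if (!is.null(rt$region)) igraph::V(g)$region <- rt$region[m]
  }
  g
}

#' Export a network as GraphML
#' @inheritParams as_igraph
#' @param path output file.
#' @export
write_graphml <- function(x, path, structure = NULL) {
  igraph::write_graph(as_igraph(x, structure), path, format = "graphml")
  invisible(path)
}

#' Export network edges as CSV
#' @param x a `ContactNetwork` or `PerturbationNetwork`.
#' @param path output file.
#' @export
write_edges_csv <- function(x, path) {
  write.csv(x$edges, path, row.names = FALSE)
  invisible(path)
}
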