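# Correlation-weighted communication paths (WISP-style): residues are
# nodes, edge weight w_ij = -log(|C_ij|), so strongly (anti)correlated
# pairs are cheap to traverse; optimal and suboptimal simple paths between
# sites are found exactly.

#' Build a correlation-weighted residue graph
#'
#' Nodes are residues located at their mass-weighted centers (taken from a
#' reference coordinate set); edges carry `w_ij = -log(|C_ij|)` (so `w = 0`
#' iff `|C| = 1`; pairs with `C = 0` have infinite weight and are absent).
#' An optional contact-network mask restricts edges to physically proximal
#' residue pairs.
#'
#' @param dcc a `DccMatrix`.
#' @param structure the `StructureModel` (dcc residues must be a subset).
#' @param coords reference coordinates for node positions (default the
#'   structure's `reference_coords`; positions are metadata only).
#' @param mask optional `ContactNetwork`; edges are kept only where the mask
#'   weight is `>= mask_min_weight`.
#' @param mask_min_weight minimum average contact count (default 1).
#' @return object of class `CorrelationGraph`: `res_index`, `weights`
#'   (matrix, `Inf` = no edge), `positions`, `graph` (igraph).
#' @export
build_graph <- function(dcc, structure, coords = structure$reference_coords,
                        mask = NULL, mask_min_weight = 1) {
  stopifnot(inherits(dcc, "DccMatrix"), inherits(structure, "StructureModel"))
  if (mask_min_weight < 0) stop("mask_min_weight must be >= 0")
  if (!all(dcc$res_index %in% structure$residues$res_index))
    stop("dcc residues not all present in structure")
  resi <- dcc$res_index
  n <- length(resi)
  W <- -log(abs(dcc$matrix))
  diag(W) <- Inf
  W[!is.finite(W) & !is.na(W)] <- Inf
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "ContactNetwork"))
    M <- matrix(FALSE, n, n)
    ed <- mask$edges[mask$edges$weight >= mask_min_weight, , drop = FALSE]
    mi <- match(ed$i, resi); mj <- match(ed$j, resi)
    ok <- !is.na(mi) & !is.na(mj)
    M[cbind(mi[ok], mj[ok])] <- TRUE
    M[cbind(mj[ok], mi[ok])] <- TRUE
    W[!M] <- Inf
  }
  pos <- NULL
  if (!is.null(coords)) {
    pos <- t(vapply(resi, function(r) {
      rows <- structure$atoms$res_index == r
      m <- structure$atoms$mass[rows]
      colSums(coords[rows, , drop = FALSE] * m) / sum(m)
    }, numeric(3)))
    rownames(pos) <- resi
  }
  ed <- which(upper.tri(W) & is.finite(W), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(resi[ed[, 1]]),
               to = as.character(resi[ed[, 2]]),
               weight = W[ed]),
    directed = FALSE,
    vertices = data.frame(name = as.character(resi)))
  structure(list(res_index = resi, weights = W, positions = pos, graph = g),
            class = "CorrelationGraph")
}

#' @export
print.CorrelationGraph <- function(x, ...) {
  cat("CorrelationGraph:", length(x$res_index), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Optimal communication path between two residues
#'
#' Minimum cumulative-weight simple path under the nonnegative
#' `-log|C|` weights (Dijkstra).
#'
#' @param graph a `CorrelationGraph`.
#' @param source,sink residue indices (global `res_index`), distinct.
#' @return list `found` (logical), `path` (residue index sequence) and
#'   `weight` (`Inf` when disconnected).
#' @export
optimal_path <- function(graph, source, sink) {
  stopifnot(inherits(graph, "CorrelationGraph"), source != sink,
            source %in% graph$res_index, sink %in% graph$res_index)
  sp <- suppressWarnings(igraph::shortest_paths(
    graph$graph, from = as.character(source), to = as.character(sink),
    weights = igraph::E(graph$graph)$weight, output = "vpath"))
  v <- sp$vpath[[1]]
  if (!length(v)) return(list(found = FALSE, path = integer(0), weight = Inf))
  p <- as.integer(igraph::V(graph$graph)$name[v])
  list(found = TRUE, path = p, weight = .path_weight(graph, p))
}

.path_weight <- function(graph, path) {
  if (length(path) < 2L) return(0)
  idx <- match(path, graph$res_index)
  sum(graph$weights[cbind(idx[-length(idx)], idx[-1])])
}

#' Suboptimal communication paths
#'
#' Exact enumeration of simple paths between source and sink, either all
#' paths within `delta` of the optimum (`mode = "within_delta"`) or the `k`
#' lowest-weight paths (`mode = "top_k"`). A depth-first search is pruned by
#' the Dijkstra distance-to-sink bound, so the contract is exactness, not
#' sampling. Ties in weight are broken by lexicographic node order.
#'
#' @param graph a `CorrelationGraph`.
#' @param source,sink residue indices.
#' @param mode `"top_k"` or `"within_delta"`.
#' @param k_or_delta number of paths (`top_k`, >= 1) or weight slack
#'   (`within_delta`, >= 0).
#' @return object of class `PathSet`: `paths` (list of residue sequences),
#'   `weights` (non-decreasing), `source`, `sink`, `mode`.
#' @export
suboptimal_paths <- function(graph, source, sink,
                             mode = c("top_k", "within_delta"), k_or_delta) {
  mode <- match.arg(mode)
  opt <- optimal_path(graph, source, sink)
  if (!opt$found) stop("no path between ", source, " and ", sink)
  eps <- 1e-9
  if (mode == "within_delta") {
    delta <- k_or_delta
    if (delta < 0) stop("delta must be >= 0")
    res <- .bounded_paths(graph, source, sink, opt$weight + delta + eps)
  } else {
    k <- as.integer(k_or_delta)
    if (k < 1L) stop("k must be >= 1")
    fin <- graph$weights[is.finite(graph$weights) & upper.tri(graph$weights)]
    maxw <- sum(fin)  # weight of any simple path is bounded by the edge sum
    delta <- max(opt$weight, 1e-6)
    repeat {
      res <- .bounded_paths(graph, source, sink, opt$weight + delta + eps)
      if (length(res$paths) >= k || opt$weight + delta >= maxw) break
      delta <- delta * 2
    }
    res$paths <- res$paths[seq_len(min(k, length(res$paths)))]
    res$weights <- res$weights[seq_len(length(res$paths))]
  }
  structure(list(paths = res$paths, weights = res$weights,
                 source = source, sink = sink, mode = mode,
                 optimal_weight = opt$weight),
            class = "PathSet")
}

# all simple paths with weight <= limit, DFS pruned by distance-to-sink
.bounded_paths <- function(graph, source, sink, limit) {
  resi <- graph$res_index
  n <- length(resi)
  W <- graph$weights
  s <- match(source, resi); t <- match(sink, resi)
  dist_to_sink <- as.numeric(igraph::distances(
    graph$graph, v = igraph::V(graph$graph),
    to = as.character(sink), weights = igraph::E(graph$graph)$weight))
  names(dist_to_sink) <- igraph::V(graph$graph)$name
  dts <- dist_to_sink[as.character(resi)]
  paths <- list(); weights <- numeric(0)
  visited <- logical(n)
  stack_path <- integer(0)
  dfs <- function(u, w) {
    if (w + dts[u] > limit) return()
    visited[u] <<- TRUE
    stack_path <<- c(stack_path, u)
    if (u == t) {
      paths[[length(paths) + 1L]] <<- resi[stack_path]
      weights <- c(weights, w)
      weights[length(paths)] <<- w
    } else {
      for (v in which(is.finite(W[u, ]))) {
        if (!visited[v]) dfs(v, w + W[u, v])
      }
    }
    visited[u] <<- FALSE
    stack_path <<- stack_path[-length(stack_path)]
  }
  dfs(s, 0)
  if (!length(paths)) return(list(paths = list(), weights = numeric(0)))
  ord <- .order_paths(paths, weights)
  list(paths = paths[ord], weights = weights[ord])
}

# order by weight, then lexicographically by node sequence
.order_paths <- function(paths, weights) {
  keys <- vapply(paths, function(p)
    paste(formatC(p, width = 9, flag = "0"), collapse = "/"), character(1))
  ord <- order(keys)
  ord[order(round(weights[ord] / 1e-9) * 1e-9)]
}

#' @export
print.PathSet <- function(x, ...) {
  cat(sprintf("PathSet: %d path(s) %d -> %d; optimal weight %.4f\n",
              length(x$paths), x$source, x$sink, x$optimal_weight))
  invisible(x)
}

#' Write a path report (TSV + JSON)
#'
#' @param x a `PathSet`.
#' @param structure optional `StructureModel` for subunit-tagged labels.
#' @param tsv,json output paths (either may be `NULL`).
#' @export
write_path_report <- function(x, structure = NULL, tsv = NULL, json = NULL) {
  lab <- function(p) {
    if (is.null(structure)) return(paste(p, collapse = "-"))
    rt <- structure$residues
    paste(vapply(p, function(r) {
      m <- match(r, rt$res_index)
      sprintf("%s:%s%d", rt$subunit[m], rt$resname[m], rt$resid[m])
    }, character(1)), collapse = "-")
  }
  df <- data.frame(rank = seq_along(x$paths),
                   weight = round(x$weights, 6),
                   nodes = vapply(x$paths, lab, character(1)))
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(source = x$source, sink = x$sink, mode = x$mode,
           optimal_weight = x$optimal_weight,
           paths = lapply(seq_along(x$paths), function(i)
             list(rank = i, weight = x$weights[i], nodes = x$paths[[i]]))),
      json, auto_unbox = TRUE, digits = 10)
  invisible(df)
}
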