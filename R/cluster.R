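# Conformational clustering: K-means under the pairwise superposed
# coordinate-RMSD metric, with sieved initialization (cluster every n-th
# frame, then assign the rest to the nearest centroid).

# superposed RMSD between two coordinate sets (optimal fit of a onto b),
# directly from the Kabsch singular values: e2 = |Pc|^2 + |Qc|^2 - 2 tr(DS)
.srmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$u %*% t(s$v)))
  e2 <- sum(ac^2) + sum(bc^2) - 2 * (s$d[1] + s$d[2] + d * s$d[3])
  sqrt(max(e2, 0) / nrow(a))
}

#' K-means clustering of an ensemble under the RMSD metric
#'
#' Every `sieve`-th frame is clustered by K-means in which the distance is
#' the pairwise superposed RMSD on the selection and the centroid update is
#' the superposed coordinate mean of the members; remaining frames are then
#' added to the clusters by a single nearest-centroid pass (no further
#' centroid refinement). Initialization is k-means++-style seeding in RMSD
#' space from the given seed, so the result is deterministic in
#' `(data, k, sieve, seed)`.
#'
#' @param x an `Ensemble`.
#' @param selection atom indices clustered on (default backbone).
#' @param k number of clusters (>= 1).
#' @param sieve sieve stride (default 10).
#' @param seed integer seed.
#' @param window frame window.
#' @param max_iter K-means iteration cap.
#' @return object of class `ClusterResult`: `labels` (per window frame,
#'   1..k), `frames`, `centroids` (list of `n_sel x 3` matrices),
#'   `populations` (%), `k`, `sieve`, `seed`, `objective` (within-cluster
#'   sum of squared RMSD per iteration, non-increasing).
#' @export
kmeans_rmsd <- function(x, selection = NULL, k, sieve = 10L, seed = 1L,
                        window = NULL, max_iter = 100L) {
  stopifnot(inherits(x, "Ensemble"), k >= 1L, sieve >= 1L)
  if (is.null(selection)) selection <- select_atoms(x$structure, "backbone")
  idx <- resolve_window(x, window)
  nf <- length(idx)
  if (nf < k * sieve)
    stop("need at least k * sieve frames (have ", nf, ")")
  fr <- lapply(idx, function(t)
    get_frame(x, t)[selection, , drop = FALSE])
  sieved <- seq(1L, nf, by = sieve)
  if (length(sieved) < k) stop("k exceeds sieved frame count")

  # --- k-means++ seeding on the sieved frames
  cent <- .with_seed(seed, {
    first <- sieved[sample.int(length(sieved), 1L)]
    centers <- list(fr[[first]])
    d2 <- vapply(sieved, function(i) .srmsd(fr[[i]], centers[[1]])^2,
                 numeric(1))
    while (length(centers) < k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / length(d2), length(d2))
      pick <- sieved[sample.int(length(sieved), 1L, prob = p)]
      centers[[length(centers) + 1L]] <- fr[[pick]]
      nd <- vapply(sieved, function(i)
        .srmsd(fr[[i]], centers[[length(centers)]])^2, numeric(1))
      d2 <- pmin(d2, nd)
    }
    centers
  })

  # --- Lloyd iterations on the sieved frames
  assign_nearest <- function(frames_i, centers) {
    vapply(frames_i, function(i) {
      d <- vapply(centers, function(cc) .srmsd(fr[[i]], cc), numeric(1))
      which.min(d)
    }, integer(1))
  }
  obj_of <- function(frames_i, lab, centers)
    sum(vapply(seq_along(frames_i), function(q)
      .srmsd(fr[[frames_i[q]]], centers[[lab[q]]])^2, numeric(1)))
  lab_s <- assign_nearest(sieved, cent)
  objective <- obj_of(sieved, lab_s, cent)
  for (it in seq_len(max_iter)) {
    new_cent <- cent
    for (c in seq_len(k)) {
      mem <- sieved[lab_s == c]
      if (!length(mem)) next  # empty cluster keeps its centroid
      acc <- matrix(0, length(selection), 3L)
      for (i in mem) acc <- acc + .fit_coords(fr[[i]], cent[[c]],
                                              seq_len(length(selection)))
      new_cent[[c]] <- acc / length(mem)
    }
    new_lab <- assign_nearest(sieved, new_cent)
    objective <- c(objective, obj_of(sieved, new_lab, new_cent))
    converged <- identical(new_lab, lab_s)
    cent <- new_cent; lab_s <- new_lab
    if (converged) break
  }

  # --- single nearest-centroid pass for the non-sieved frames
  labels <- integer(nf)
  labels[sieved] <- lab_s
  rest <- setdiff(seq_len(nf), sieved)
  if (length(rest)) labels[rest] <- assign_nearest(rest, cent)

  pop <- 100 * tabulate(labels, k) / nf
  structure(list(labels = labels, frames = idx, centroids = cent,
                 populations = pop, k = k, sieve = sieve, seed = seed,
                 selection = selection, objective = objective),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: k=%d, sieve=%d, populations (%%): %s\n",
              x$k, x$sieve,
              paste(sprintf("%.1f", sort(x$populations, decreasing = TRUE)),
                    collapse = ", ")))
  invisible(x)
}

#' Cluster populations, sorted descending
#'
#' @param result a `ClusterResult`.
#' @return data.frame `cluster` (stable id), `population` (%), sorted by
#'   decreasing population.
#' @export
populations <- function(result) {
  stopifnot(inherits(result, "ClusterResult"))
  ord <- order(result$populations, decreasing = TRUE)
  data.frame(cluster = ord, population = result$populations[ord])
}

#' Representative frame of a cluster
#'
#' The member frame with minimum superposed RMSD to the cluster centroid;
#' ties resolve to the lowest frame index.
#'
#' @param result a `ClusterResult`.
#' @param x the clustered `Ensemble`.
#' @param cluster_id cluster (1..k).
#' @return frame index into the ensemble.
#' @export
representative_frame <- function(result, x, cluster_id) {
  stopifnot(inherits(result, "ClusterResult"),
            cluster_id >= 1L, cluster_id <= result$k)
  mem <- which(result$labels == cluster_id)
  if (!length(mem)) stop("cluster ", cluster_id, " is empty")
  cc <- result$centroids[[cluster_id]]
  d <- vapply(mem, function(q)
    .srmsd(get_frame(x, result$frames[q])[result$selection, , drop = FALSE],
           cc), numeric(1))
  result$frames[mem[which.min(d)]]  # which.min takes the first minimum
}

#' Write a frame-to-cluster table and JSON summary
#'
#' @param result a `ClusterResult`.
#' @param x the clustered `Ensemble`.
#' @param csv,json output files (either may be `NULL`).
#' @export
write_cluster_report <- function(result, x, csv = NULL, json = NULL) {
  if (!is.null(csv))
    write.csv(data.frame(frame = result$frames, cluster = result$labels),
              csv, row.names = FALSE)
  if (!is.null(json)) {
    pops <- populations(result)
    jsonlite::write_json(
      list(k = result$k, sieve = result$sieve, seed = result$seed,
           populations = lapply(seq_len(nrow(pops)), function(i)
             list(cluster = pops$cluster[i],
                  population = round(pops$population[i], 4),
                  representative_frame =
                    representative_frame(result, x, pops$cluster[i]))) ),
      json, auto_unbox = TRUE, digits = 10)
  }
  invisible(result)
}
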