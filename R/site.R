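# Binding-site pre-organization and interaction-geometry statistics:
# site-restricted RMSD distributions with peak detection, group-minimum
# distance series (salt bridges / H-bonds), two-orientation occupancy.

#' Site-restricted RMSD distribution
#'
#' Frames are superposed globally (on `fit_selection`, default backbone)
#' onto the reference, then the RMSD is measured over the site selection
#' only. The per-frame values are summarized as a histogram (0.1 Angstrom
#' bins) and a Gaussian-kernel density (Silverman bandwidth) whose local
#' maxima above a prominence floor are reported as peaks -- the shape of
#' the distribution is what distinguishes a pre-organized site (one sharp
#' peak near the bound-state geometry) from a loose or bimodal one.
#'
#' @param x an `Ensemble`.
#' @param reference `n_atoms x 3` matrix (conventionally the window-average
#'   structure of the fully bound state) or a frame index.
#' @param site_selection atom indices of the site.
#' @param fit_selection atom indices for the global fit (default backbone).
#' @param window frame window.
#' @param min_prominence peak floor as a fraction of the density maximum
#'   (default 0.05).
#' @return object of class `SiteRmsdDistribution`: `values` (Angstrom),
#'   `histogram`, `density`, `peaks` (Angstrom, ascending).
#' @export
site_rmsd_distribution <- function(x, reference, site_selection,
                                   fit_selection = NULL, window = NULL,
                                   min_prominence = 0.05) {
  stopifnot(inherits(x, "Ensemble"), length(site_selection) >= 1L)
  ref <- if (is.matrix(reference)) reference else get_frame(x, reference)
  if (is.null(fit_selection))
    fit_selection <- select_atoms(x$structure, "backbone")
  idx <- resolve_window(x, window)
  vals <- vapply(idx, function(t) {
    fr <- .fit_coords(get_frame(x, t), ref, fit_selection)
    .rmsd(fr[site_selection, , drop = FALSE],
          ref[site_selection, , drop = FALSE])
  }, numeric(1))
  breaks <- seq(0, max(vals, 0.1) + 0.1, by = 0.1)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  if (stats::var(vals) > 0) {
    dens <- stats::density(vals, bw = "nrd0", from = 0)
    ymax <- max(dens$y)
    loc <- which(diff(sign(diff(dens$y))) == -2) + 1L
    loc <- loc[dens$y[loc] >= min_prominence * ymax]
    peaks <- sort(dens$x[loc])
  } else {
    dens <- NULL
    peaks <- vals[1]
  }
  structure(list(values = vals, frames = idx, histogram = h,
                 density = dens, peaks = peaks),
            class = "SiteRmsdDistribution")
}

#' @export
print.SiteRmsdDistribution <- function(x, ...) {
  cat(sprintf("SiteRmsdDistribution: %d frames, mean %.2f Angstrom, peaks at %s\n",
              length(x$values), mean(x$values),
              paste(sprintf("%.2f", x$peaks), collapse = ", ")))
  invisible(x)
}

#' Fraction of frames resembling the reference state
#'
#' The fraction of frames whose site RMSD is at or below a cutoff. When no
#' cutoff is given it is placed at the density minimum (valley) between the
#' first two peaks of a bimodal distribution; the cutoff actually used is
#' always returned so the number is interpretable.
#'
#' @param dist a `SiteRmsdDistribution`.
#' @param cutoff Angstrom, > 0; `NULL` for the automatic valley rule.
#' @return list `fraction` (in `[0,1]`, monotone non-decreasing in the
#'   cutoff) and `cutoff` (Angstrom).
#' @export
overlap_fraction <- function(dist, cutoff = NULL) {
  stopifnot(inherits(dist, "SiteRmsdDistribution"))
  if (!length(dist$values)) stop("no frames in distribution")
  if (is.null(cutoff)) {
    if (length(dist$peaks) < 2L || is.null(dist$density))
      stop("automatic cutoff needs a bimodal distribution; supply cutoff=")
    p1 <- dist$peaks[1]; p2 <- dist$peaks[2]
    between <- dist$density$x > p1 & dist$density$x < p2
    cutoff <- dist$density$x[between][which.min(dist$density$y[between])]
  }
  if (cutoff <= 0) stop("cutoff must be > 0")
  list(fraction = mean(dist$values <= cutoff), cutoff = cutoff)
}

#' Per-frame minimum distance between two atom groups
#'
#' The group-minimum heavy-atom distance is the standard geometric proxy
#' for a salt bridge or hydrogen bond (e.g. arginine guanidinium N atoms vs
#' aspartate carboxylate O atoms); angles are not used.
#'
#' @param x an `Ensemble`.
#' @param group_a,group_b disjoint, non-empty atom index vectors.
#' @param window frame window.
#' @param contact_cutoff occupancy cutoff (Angstrom, default 4.0).
#' @return object of class `DistanceStats`: `values` (Angstrom per frame),
#'   `mean`, `sd` (population), `occupancy` (fraction of frames with
#'   distance below the cutoff), `cutoff`.
#' @export
pair_distance_stats <- function(x, group_a, group_b, window = NULL,
                                contact_cutoff = 4.0) {
  stopifnot(inherits(x, "Ensemble"),
            length(group_a) >= 1L, length(group_b) >= 1L)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap")
  idx <- resolve_window(x, window)
  vals <- vapply(idx, function(t) {
    fr <- get_frame(x, t)
    .min_cross_dist(fr[group_a, , drop = FALSE], fr[group_b, , drop = FALSE])
  }, numeric(1))
  structure(list(values = vals, frames = idx, mean = mean(vals),
                 sd = sqrt(mean((vals - mean(vals))^2)),
                 occupancy = mean(vals < contact_cutoff),
                 cutoff = contact_cutoff),
            class = "DistanceStats")
}

.min_cross_dist <- function(a, b) {
  # exhaustive pairwise minimum; group sizes are small (side-chain tips)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' @export
print.DistanceStats <- function(x, ...) {
  cat(sprintf("DistanceStats: %.2f +/- %.2f Angstrom, occupancy %.1f%% (< %.1f)\n",
              x$mean, x$sd, 100 * x$occupancy, x$cutoff))
  invisible(x)
}

#' Two-orientation occupancy of a switching residue
#'
#' Each frame is assigned to the partner (A or B) whose minimum heavy-atom
#' distance to the switch group is smaller, provided that distance is at or
#' below the cutoff; frames within reach of neither are "neither". This
#' captures a side chain (e.g. an arginine) alternating between two salt
#' bridge partners.
#'
#' @param x an `Ensemble`.
#' @param switch_group atom indices of the switching residue's interacting
#'   group.
#' @param partner_a,partner_b disjoint atom index vectors.
#' @param contact_cutoff assignment cutoff (Angstrom), > 0.
#' @param window frame window.
#' @return object of class `OrientationSplit`: `assignment` (factor
#'   A/B/neither per frame), `fraction_of_all` and `fraction_of_assigned`
#'   (named A/B percentages).
#' @export
orientation_occupancy <- function(x, switch_group, partner_a, partner_b,
                                  contact_cutoff = 4.0, window = NULL) {
  stopifnot(inherits(x, "Ensemble"), contact_cutoff > 0)
  if (length(intersect(partner_a, partner_b)))
    stop("partner groups overlap")
  idx <- resolve_window(x, window)
  da <- vapply(idx, function(t) {
    fr <- get_frame(x, t)
    .min_cross_dist(fr[switch_group, , drop = FALSE],
                    fr[partner_a, , drop = FALSE])
  }, numeric(1))
  db <- vapply(idx, function(t) {
    fr <- get_frame(x, t)
    .min_cross_dist(fr[switch_group, , drop = FALSE],
                    fr[partner_b, , drop = FALSE])
  }, numeric(1))
  nearest <- ifelse(da <= db, "A", "B")
  within <- pmin(da, db) <= contact_cutoff
  assignment <- factor(ifelse(within, nearest, "neither"),
                       levels = c("A", "B", "neither"))
  n <- length(idx); na <- sum(assignment == "A"); nb <- sum(assignment == "B")
  nass <- na + nb
  structure(list(assignment = assignment,
                 fraction_of_all = c(A = 100 * na / n, B = 100 * nb / n),
                 fraction_of_assigned = if (nass > 0)
                   c(A = 100 * na / nass, B = 100 * nb / nass)
                 else c(A = 0, B = 0),
                 cutoff = contact_cutoff),
            class = "OrientationSplit")
}

#' @export
print.OrientationSplit <- function(x, ...) {
  cat(sprintf("OrientationSplit: A %.1f%% / B %.1f%% of all frames (cutoff %.1f)\n",
              x$fraction_of_all["A"], x$fraction_of_all["B"], x$cutoff))
  invisible(x)
}
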