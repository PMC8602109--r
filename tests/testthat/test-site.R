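# binding-site pre-organization distributions and interaction geometry

test_that("site RMSD distribution degenerates, splits and peaks correctly", {
  st <- synthetic_structure(10)
  ref <- st$reference_coords
  site <- select_atoms(st, "heavy", res_index = 8:9)
  bb <- select_atoms(st, "backbone")
  # ensemble = reference repeated: all values 0, single peak at 0
  e0 <- ensemble(st, array(rep(ref, each = 5), c(5, nrow(ref), 3)))
  d0 <- site_rmsd_distribution(e0, ref, site, fit_selection = bb)
  expect_equal(d0$values, rep(0, 5))
  expect_equal(d0$peaks, 0)

  # planted bimodal site: half the frames carry a 2.5 A site displacement
  set.seed(3)
  nfr <- 4000
  coords <- array(rep(ref, each = nfr), c(nfr, nrow(ref), 3)) +
    array(rnorm(nfr * nrow(ref) * 3, sd = 0.08), c(nfr, nrow(ref), 3))
  shifted <- seq_len(nfr) > nfr * 0.6          # 40/60 mixture
  rows <- st$atoms$res_index %in% 8:9
  coords[shifted, rows, 2] <- coords[shifted, rows, 2] + 2.5
  e <- ensemble(st, coords)
  # anchor the global fit on the non-site residues so the planted site
  # displacement is not partially absorbed by the superposition
  anchor <- select_atoms(st, "calpha", res_index = 1:7)
  db <- site_rmsd_distribution(e, ref, site, fit_selection = anchor)
  expect_gte(length(db$peaks), 2L)
  # peak separation matches the planted displacement within a bin or so
  expect_lt(abs((db$peaks[2] - db$peaks[1]) - 2.5), 0.3)

  # unimodal case: peak location against an independent sampling oracle
  set.seed(4)
  sigma <- 0.25; m <- length(site)
  vals <- replicate(20000, sqrt(mean(rowSums(
    matrix(rnorm(3 * m, sd = sigma), m, 3)^2))))
  od <- density(vals, bw = "nrd0")
  oracle_peak <- od$x[which.max(od$y)]
  coords1 <- array(rep(ref, each = 2000), c(2000, nrow(ref), 3))
  coords1[, site, ] <- coords1[, site, ] +
    array(rnorm(2000 * m * 3, sd = sigma), c(2000, m, 3))
  du <- site_rmsd_distribution(ensemble(st, coords1), ref, site,
                               fit_selection = bb)
  expect_lt(abs(du$peaks[which.max(du$density$y[match(
    du$peaks, du$density$x)])] - oracle_peak) / oracle_peak, 0.05)

  # overlap fractions: bounds, valley rule, monotonicity
  expect_equal(overlap_fraction(db, cutoff = 100)$fraction, 1)
  expect_equal(overlap_fraction(db, cutoff = 1e-6)$fraction, 0)
  ov <- overlap_fraction(db)                    # automatic valley
  expect_lt(abs(ov$fraction - 0.60), 0.02)
  expect_gt(ov$cutoff, db$peaks[1]); expect_lt(ov$cutoff, db$peaks[2])
  cuts <- seq(0.2, 4, by = 0.2)
  fr <- vapply(cuts, function(cc) overlap_fraction(db, cc)$fraction,
               numeric(1))
  expect_false(is.unsorted(fr))
})

test_that("pair distance statistics match closed forms and the oracle", {
  st <- synthetic_structure(6)
  ref <- st$reference_coords
  ga <- select_atoms(st, "heavy", res_index = 1)
  gb <- select_atoms(st, "heavy", res_index = 4)
  # static toy at a known minimum distance
  co <- ref
  co[gb, ] <- matrix(rep(c(3, 0, 0), each = length(gb)), ncol = 3) +
    sweep(ref[gb, , drop = FALSE], 2, ref[gb[1], ])  # gb[1] at (3,0,0)
  co[ga, ] <- sweep(ref[ga, , drop = FALSE], 2, ref[ga[1], ])  # ga[1] at 0
  e <- ensemble(st, array(rep(co, each = 3), c(3, nrow(co), 3)))
  ds <- pair_distance_stats(e, ga, gb)
  oracle <- min(as.matrix(dist(co))[ga, gb])
  expect_equal(ds$mean, oracle, tolerance = 1e-12)
  expect_equal(ds$sd, 0)

  # two frames at 2 and 4 A: mean 3, population SD 1
  co2 <- co; co2[gb, 1] <- co2[gb, 1] + (2 - oracle)
  co4 <- co; co4[gb, 1] <- co4[gb, 1] + (4 - oracle)
  e2 <- ensemble(st, aperm(array(c(co2, co4), c(nrow(co), 3, 2)), c(3, 1, 2)))
  ds2 <- pair_distance_stats(e2, ga, gb, contact_cutoff = 3)
  expect_equal(ds2$values, c(2, 4), tolerance = 1e-9)
  expect_equal(ds2$mean, 3, tolerance = 1e-9)
  expect_equal(ds2$sd, 1, tolerance = 1e-9)
  expect_equal(ds2$occupancy, 0.5)
  # stored series reproduces the summary exactly
  expect_equal(ds2$mean, mean(ds2$values), tolerance = 1e-12)
  expect_equal(ds2$sd, sqrt(mean((ds2$values - mean(ds2$values))^2)),
               tolerance = 1e-12)

  # random multi-atom groups against the exhaustive pairwise oracle
  set.seed(6)
  for (r in 1:5) {
    co_r <- ref + matrix(rnorm(length(ref), sd = 1), nrow(ref), 3)
    er <- ensemble(st, array(rep(co_r, each = 2), c(2, nrow(ref), 3)))
    got <- pair_distance_stats(er, ga, gb)$values[1]
    expect_equal(got, min(as.matrix(dist(co_r))[ga, gb]), tolerance = 1e-10)
  }
  expect_error(pair_distance_stats(e, ga, ga), "overlap")
})

test_that("orientation occupancy splits, saturates and ignores rigid motion", {
  st <- synthetic_structure(9)
  ref <- st$reference_coords
  sw <- select_atoms(st, "heavy", res_index = 5)
  pa <- select_atoms(st, "heavy", res_index = 1)
  pb <- select_atoms(st, "heavy", res_index = 9)
  # switch group at the origin; partner A along +x, partner B along -x,
  # one of them at contact range and the other far away
  place <- function(near_a, gap = 2.5, far = 30) {
    at <- function(g, shift) sweep(ref[g, , drop = FALSE], 2, ref[g[1], ]) +
      matrix(rep(shift, each = length(g)), ncol = 3)
    co <- ref
    co[sw, ] <- at(sw, c(0, 0, 0))
    co[pa, ] <- at(pa, c(if (near_a) gap else far, 0, 0))
    co[pb, ] <- at(pb, c(-(if (near_a) far else gap), 0, 0))
    co
  }
  nfr <- 1000; n_a <- 550
  coords <- array(NA_real_, c(nfr, nrow(ref), 3))
  for (t in seq_len(nfr)) coords[t, , ] <- place(t <= n_a)
  e <- ensemble(st, coords)
  os <- orientation_occupancy(e, sw, pa, pb, contact_cutoff = 4)
  expect_equal(unname(os$fraction_of_all["A"]), 55, tolerance = 2)
  expect_equal(unname(os$fraction_of_all["B"]), 45, tolerance = 2)
  expect_equal(sum(os$fraction_of_assigned), 100, tolerance = 1e-9)

  # all frames near A only
  eA <- ensemble(st, coords[seq_len(n_a), , , drop = FALSE])
  osA <- orientation_occupancy(eA, sw, pa, pb, contact_cutoff = 4)
  expect_equal(unname(osA$fraction_of_all), c(100, 0))

  # beyond the cutoff from both partners: everything is "neither"
  os0 <- orientation_occupancy(e, sw, pa, pb, contact_cutoff = 1)
  expect_equal(unname(os0$fraction_of_all), c(0, 0))
  expect_true(all(os0$assignment == "neither"))

  # invariant under a global rigid motion of every frame
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  e_rot <- e
  for (t in seq_len(nfr))
    e_rot$coords[t, , ] <- sweep(coords[t, , ] %*% R, 2, c(4, -6, 2), "+")
  os_rot <- orientation_occupancy(e_rot, sw, pa, pb, contact_cutoff = 4)
  expect_identical(os_rot$assignment, os$assignment)
  expect_error(orientation_occupancy(e, sw, pa, pa), "overlap")
})
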