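# structures, selections, trajectory I/O, superposition, RMSD/RMSF

test_that("PDB reader resolves residues, hydrogens and HETATM ligands", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), f)
  st <- read_structure(f, subunit_map = c(A = "alpha"))
  expect_equal(nrow(st$residues), 3L)           # 2 GLY + 1 ligand
  expect_equal(sum(st$atoms$is_heavy), 10L)     # 11 atoms - 1 hydrogen
  expect_equal(st$residues$subunit, rep("alpha", 3))
  # ligand retained under its own residue but absent from backbone/calpha
  bb <- select_atoms(st, "backbone")
  expect_false(any(st$atoms$is_het[bb]))
  expect_equal(length(bb), 8L)                  # N,CA,C,O for two residues
  expect_equal(length(select_atoms(st, "calpha")), 2L)
  expect_error(select_atoms(st, "calpha", chain = "Z"), "zero atoms")
})

test_that("multi-model PDB and DCD round-trip, and units normalize", {
  spec <- planted_spec(5, lambdas = 0.5, noise_sigma = 0.1)
  e <- make_gaussian_ensemble(spec, 3, seed = 2)
  fp <- withr::local_tempfile(fileext = ".pdb")
  fd <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(e, fp)
  write_trajectory(e, fd)
  ep <- read_trajectory(e$structure, fp)
  ed <- read_trajectory(e$structure, fd)
  expect_equal(n_frames(ep), 3L)
  expect_lt(max(abs(ep$coords - e$coords)), 5e-4)   # PDB prints 3 decimals
  expect_lt(max(abs(ed$coords - e$coords)), 1e-4)   # float32
  # cross-format agreement after both normalizations
  expect_lt(max(abs(ep$coords - ed$coords)), 6e-4)
  # nm-scaled input normalized back to Angstrom via scale=10
  enm <- e; enm$coords <- e$coords / 10
  fnm <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(enm, fnm)
  eA <- read_trajectory(e$structure, fnm, scale = 10)
  expect_lt(max(abs(eA$coords - e$coords)), 1e-3)
  # atom-count mismatch rejected
  st2 <- synthetic_structure(6)
  expect_error(read_trajectory(st2, fp), "does not match")
})

test_that("windows resolve as half-open ranges, trailing frames and times", {
  spec <- planted_spec(5, lambdas = 0.5, noise_sigma = 0.1)
  e <- make_gaussian_ensemble(spec, 10, seed = 1, frame_stride = 2)
  expect_equal(resolve_window(e, NULL), 1:10)
  expect_equal(resolve_window(e, c(3, 7)), 3:6)
  expect_equal(resolve_window(e, last_frames(4)), 7:10)
  expect_equal(resolve_window(e, last_ns(6)), 8:10)  # 3 frames at 2 ns
  expect_error(resolve_window(e, c(8, 20)), "out of range")
})

test_that("superposition removes rigid motion with a proper rotation", {
  spec <- planted_spec(6, lambdas = 0.5, noise_sigma = 0.2)
  e <- make_gaussian_ensemble(spec, 4, seed = 3)
  ref <- get_frame(e, 1)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(ref %*% R, 2, c(5, -2, 7), "+")
  e2 <- e; e2$coords[2, , ] <- moved
  fit <- superpose(e2, reference = 1L)
  expect_lt(trajan:::.rmsd(get_frame(fit, 2), ref), 1e-8)

  # chirality preserved (no reflection): signed tetrahedron volume keeps sign
  vol <- function(m) det(cbind(m[2, ] - m[1, ], m[3, ] - m[1, ],
                               m[4, ] - m[1, ]))
  for (t in 1:4)
    expect_gt(vol(get_frame(fit, t)[1:4, ]) * vol(ref[1:4, ]), 0)

  # RMSD after superposition never exceeds RMSD before
  rs_fit <- rmsd_series(e, reference = 1L, fit = TRUE)
  rs_raw <- rmsd_series(e, reference = 1L, fit = FALSE)
  expect_true(all(rs_fit$values <= rs_raw$values + 1e-12))
})

test_that("superposed RMSD matches the quaternion oracle", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    P <- matrix(rnorm(3 * n, sd = 3), n, 3)
    Q <- matrix(rnorm(3 * n, sd = 3), n, 3)
    got <- trajan:::.rmsd(trajan:::.fit_coords(P, Q, seq_len(n)), Q)
    expect_equal(got, quat_rmsd_oracle(P, Q), tolerance = 1e-6)
  }
})

test_that("rmsd_series closed forms and self-consistency hold", {
  spec <- planted_spec(5, lambdas = 0.5, noise_sigma = 0)
  st <- spec$structure
  ref <- st$reference_coords
  coords <- array(rep(ref, each = 4), c(4, nrow(ref), 3))
  e <- ensemble(st, coords)
  expect_equal(rmsd_series(e, reference = 1L)$values, rep(0, 4))

  # one atom displaced by d in one frame, no fitting: RMSD = d / sqrt(N)
  d <- 1.7
  e$coords[3, 2, 1] <- e$coords[3, 2, 1] + d
  rs <- rmsd_series(e, reference = ref, fit = FALSE)
  expect_equal(rs$values[3], d / sqrt(nrow(ref)), tolerance = 1e-12)
  expect_equal(rs$values[c(1, 2, 4)], rep(0, 3))

  # mean/sd agree with direct recomputation (population SD)
  expect_equal(rs$mean, mean(rs$values), tolerance = 1e-15)
  expect_equal(rs$sd, sqrt(mean((rs$values - mean(rs$values))^2)),
               tolerance = 1e-15)
})

test_that("average_structure interpolates and converges", {
  st <- synthetic_structure(5)
  ref <- st$reference_coords
  same <- ensemble(st, array(rep(ref, each = 3), c(3, nrow(ref), 3)))
  expect_equal(average_structure(same), ref, ignore_attr = TRUE,
               tolerance = 1e-12)

  # two frames symmetric about a midpoint (no fit: pure translation would
  # be removed by fitting, so use an internal symmetric distortion)
  delta <- matrix(rnorm(nrow(ref) * 3, sd = 0.1), ncol = 3)
  delta <- delta - matrix(colMeans(delta), nrow(ref), 3, byrow = TRUE)
  two <- ensemble(st, aperm(array(c(ref + delta, ref - delta),
                                  c(nrow(ref), 3, 2)), c(3, 1, 2)))
  expect_equal(average_structure(two, fit = FALSE), ref,
               ignore_attr = TRUE, tolerance = 1e-10)

  # CLT: mean of a Gaussian ensemble approaches the reference
  spec <- planted_spec(5, lambdas = 0.2, noise_sigma = 0.1)
  e <- make_gaussian_ensemble(spec, 1e4, seed = 8)
  avg <- average_structure(e, fit = FALSE)
  sd_max <- sqrt(0.2 + 0.1^2)      # coordinate SD upper bound
  expect_lt(max(abs(avg - spec$reference)), 5 * sd_max / sqrt(1e4))
})

test_that("rmsf_profile closed forms, zero cases and invariances hold", {
  st <- synthetic_structure(6)
  ref <- st$reference_coords
  nat <- nrow(ref)
  static <- ensemble(st, array(rep(ref, each = 5), c(5, nat, 3)))
  pr <- rmsf_profile(list(static, static, static))
  expect_equal(pr$mean, rep(0, 6))
  expect_equal(pr$sd, rep(0, 6))

  # residue 3 CA oscillates +/- a along x; fit anchored on other residues
  a <- 0.9
  ca <- select_atoms(st, "calpha")
  coords <- array(rep(ref, each = 8), c(8, nat, 3))
  s <- rep(c(1, -1), 4)
  for (t in 1:8) coords[t, ca[3], 1] <- ref[ca[3], 1] + a * s[t]
  e <- ensemble(st, coords)
  anchor <- setdiff(ca, ca[3])
  pr <- rmsf_profile(list(e), selection = ca, fit_selection = anchor)
  expect_equal(pr$per_replica[3, 1], a, tolerance = 0.01)
  expect_lt(max(pr$per_replica[-3, 1]), 1e-10)

  # invariant under a global rigid motion of every frame
  th <- 0.5
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  e2 <- e
  for (t in 1:8)
    e2$coords[t, , ] <- sweep(get_frame(e, t) %*% R, 2, c(3, 3, 3), "+")
  pr2 <- rmsf_profile(list(e2), selection = ca, fit_selection = anchor)
  expect_equal(pr2$per_replica, pr$per_replica, tolerance = 1e-8)
})
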