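# synthetic-data generators: planted modes, two-state pairs, mixtures

test_that("gaussian generator honours degenerate and deterministic contracts", {
  st <- synthetic_structure(6)
  spec0 <- gaussian_ensemble_spec(st)  # zero modes, zero noise
  e0 <- make_gaussian_ensemble(spec0, 5, seed = 1)
  for (t in 1:5)
    expect_equal(get_frame(e0, t), st$reference_coords,
                 ignore_attr = TRUE, tolerance = 0)

  spec <- planted_spec(6, lambdas = 1.0, noise_sigma = 0.2)
  e1 <- make_gaussian_ensemble(spec, 50, seed = 42)
  e2 <- make_gaussian_ensemble(spec, 50, seed = 42)
  expect_identical(e1$coords, e2$coords)
  e3 <- make_gaussian_ensemble(spec, 50, seed = 43)
  expect_false(identical(e1$coords, e3$coords))
})

test_that("per-coordinate displacement variance follows the planted mode", {
  spec <- planted_spec(8, lambdas = 1.0, noise_sigma = 0)
  e <- make_gaussian_ensemble(spec, 1e4, seed = 7)
  v <- matrix(spec$modes[, 1], ncol = 3, byrow = TRUE)
  dx <- sweep(e$coords[, , 1], 2, spec$reference[, 1])
  # variance of atom coordinate = lambda * mode_component^2
  comp <- v[, 1]
  big <- which(comp^2 > 0.01)    # avoid relative comparison at tiny variance
  sampv <- apply(dx[, big], 2, var)
  expect_true(all(abs(sampv / comp[big]^2 - 1) < 0.10))
})

test_that("spec validation rejects malformed modes and parameters", {
  st <- synthetic_structure(6)
  m <- cbind(plant_mode(st, rep(1, 6)), plant_mode(st, rep(1, 6)))
  expect_error(gaussian_ensemble_spec(st, m, c(1, 1)), "orthonormal")
  good <- plant_mode(st, rep(1, 6))
  expect_error(gaussian_ensemble_spec(st, cbind(good), c(-1)), "positive")
  expect_error(gaussian_ensemble_spec(st, cbind(good, orthonormalize_modes(
    project_out_rigid_body(plant_mode(st, c(1, -1, 1, -1, 1, -1)),
                           st$reference_coords))), c(1, 2)),
    "non-increasing")
  expect_error(gaussian_ensemble_spec(st, cbind(good), 1, noise_sigma = -1),
               ">= 0")
})

test_that("sample covariance converges to the model covariance", {
  spec <- planted_spec(10, lambdas = c(1.0, 0.25), noise_sigma = 0.1)
  e <- make_gaussian_ensemble(spec, 5e4, seed = 11)
  # frames x 3N in the same (x1,y1,z1,...) flattening used by modes
  n3 <- 3 * dim(e$coords)[2]
  Xf <- t(apply(e$coords, 1, function(fr) as.vector(t(fr))))
  S <- cov(Xf)
  M <- spec$modes %*% (t(spec$modes) * spec$lambdas) +
    diag(spec$noise_sigma^2, n3)
  expect_lt(norm(S - M, "F") / norm(M, "F"), 0.05)
})

test_that("analytic_dcc reproduces shared-mode limits and the model integral", {
  st <- synthetic_structure(4, atoms_per_residue = 1)
  # single shared mode, same direction on residues 1 and 2
  m_same <- plant_mode(st, c(1, 1, 0.5, 0.5), c(1, 0, 0))
  d <- analytic_dcc(gaussian_ensemble_spec(st, cbind(m_same), 1))
  expect_equal(d$matrix[1, 2], 1, tolerance = 1e-12)
  m_opp <- plant_mode(st, c(1, -1, 0.5, 0.5), c(1, 0, 0))
  d2 <- analytic_dcc(gaussian_ensemble_spec(st, cbind(m_opp), 1))
  expect_equal(d2$matrix[1, 2], -1, tolerance = 1e-12)

  # one mode + isotropic noise: compare against a dense-covariance oracle
  spec <- gaussian_ensemble_spec(st, cbind(m_same), 1, noise_sigma = 1)
  got <- analytic_dcc(spec)
  n3 <- 3 * n_atoms(st)
  Sigma <- spec$modes %*% (t(spec$modes) * spec$lambdas) + diag(1, n3)
  blk <- function(i) (3 * (i - 1) + 1):(3 * i)   # atoms == residues here
  oracle <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    cij <- sum(diag(Sigma[blk(i), blk(j)]))
    oracle[i, j] <- cij / sqrt(sum(diag(Sigma[blk(i), blk(i)])) *
                               sum(diag(Sigma[blk(j), blk(j)])))
  }
  expect_lt(max(abs(got$matrix - oracle)), 1e-6)
  # zero-variance residue rejected (residues 3 and 4 untouched, no noise)
  m_part <- plant_mode(st, c(1, -1, 0, 0), c(1, 0, 0))
  expect_error(analytic_dcc(gaussian_ensemble_spec(st, cbind(m_part), 1)),
               "zero total variance")
})

test_that("two-state pairs plant recoverable contact gains and losses", {
  spec <- planted_spec(10, lambdas = 0.25, noise_sigma = 0.05)
  # null perturbation: zero displacement, DPN empty at threshold 5
  null <- two_state_contact_spec(spec, 8:9, c(0, 0, 0))
  pr <- make_two_state_pair(null, 400, seed = 5)
  pn <- perturbation(dynamical_contact_network(pr$a),
                     dynamical_contact_network(pr$b), threshold = 5)
  expect_identical(nrow(pn$edges), 0L)

  # 6 A displacement: recovered losses equal the static ground truth
  ts <- two_state_contact_spec(spec, 8:9, c(0, 6, 0))
  pr <- make_two_state_pair(ts, 800, seed = 5)
  na <- dynamical_contact_network(pr$a); nb <- dynamical_contact_network(pr$b)
  pn <- perturbation(na, nb, threshold = 5)
  gt <- contact_ground_truth(ts)
  gt <- gt[abs(gt$delta) > 5, ]
  expect_equal(pn$edges$i, gt$i)
  expect_equal(pn$edges$j, gt$j)
  expect_true(all(pn$edges$sign == ifelse(gt$delta > 0, "gain", "loss")))

  # swapping the states flips every sign
  pn_rev <- perturbation(nb, na, threshold = 5)
  expect_equal(pn_rev$edges$delta, -pn$edges$delta)

  # block validation
  expect_error(two_state_contact_spec(spec, integer(0), c(1, 0, 0)), "subset")
  expect_error(two_state_contact_spec(spec, 1:10, c(1, 0, 0)), "subset")
})

test_that("conformer mixtures sample weights and are exact at zero jitter", {
  mx <- separable_mixture(6, m = 2, weights = c(0.8, 0.2), jitter = 0)
  out <- make_conformer_mixture(mx, 1e4, seed = 9)
  frac <- mean(out$labels == 1)
  expect_lt(abs(frac - 0.8), 0.02)
  for (t in c(1, 500, 10000))
    expect_equal(get_frame(out$ensemble, t),
                 mx$conformers[[out$labels[t]]], ignore_attr = TRUE)
  out2 <- make_conformer_mixture(mx, 1e4, seed = 9)
  expect_identical(out$labels, out2$labels)
  expect_identical(out$ensemble$coords, out2$ensemble$coords)
  expect_error(conformer_mixture_spec(mx$structure, mx$conformers[1],
                                      1), "at least 2")
  expect_error(conformer_mixture_spec(mx$structure, mx$conformers,
                                      c(0.7, 0.2)), "sum to 1")
})
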