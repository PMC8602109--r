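# Independent oracles and fixture builders shared across test files.
# Everything here deliberately avoids the package's own computational path:
# quaternion superposition, explicit-loop correlation sums, recursive path
# enumeration over a raw weight matrix, contingency-table ARI.

# --- Horn quaternion superposition oracle ---------------------------------
# optimal least-squares RMSD of P onto Q via the maximum eigenvalue of the
# 4x4 quaternion matrix; independent of the SVD/Kabsch route.
quat_rmsd_oracle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  S <- t(Pc) %*% Qc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  e2 <- sum(Pc^2) + sum(Qc^2) - 2 * lam
  sqrt(max(e2, 0) / nrow(P))
}

# --- explicit-loop DCC oracle ---------------------------------------------
# Eq.-1-style evaluation with raw time loops over a frames x n x 3 array of
# representative-atom coordinates (already in a common frame).
dcc_bruteforce <- function(xyz) {
  nf <- dim(xyz)[1]; n <- dim(xyz)[2]
  mu <- apply(xyz, c(2, 3), mean)
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; vi <- 0; vj <- 0
    for (t in seq_len(nf)) {
      di <- xyz[t, i, ] - mu[i, ]; dj <- xyz[t, j, ] - mu[j, ]
      num <- num + sum(di * dj)
      vi <- vi + sum(di * di); vj <- vj + sum(dj * dj)
    }
    C[i, j] <- num / sqrt(vi * vj)
  }
  C
}

# --- exhaustive simple-path enumeration oracle ----------------------------
# all simple paths (node index sequences) between s and t over a weight
# matrix W (Inf = no edge), with total weights; plain recursion.
enumerate_paths_oracle <- function(W, s, t) {
  n <- nrow(W)
  paths <- list(); weights <- numeric(0)
  rec <- function(u, visited, trail, w) {
    if (u == t) {
      paths[[length(paths) + 1L]] <<- trail
      weights[length(paths)] <<- w
      return()
    }
    for (v in seq_len(n)) {
      if (!visited[v] && is.finite(W[u, v])) {
        visited[v] <- TRUE
        rec(v, visited, c(trail, v), w + W[u, v])
        visited[v] <- FALSE
      }
    }
  }
  visited <- logical(n); visited[s] <- TRUE
  rec(s, visited, s, 0)
  list(paths = paths, weights = weights)
}

# --- adjusted Rand index ---------------------------------------------------
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab))); sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# --- fixture builders ------------------------------------------------------

# Gaussian spec with k planted modes, rigid-body-free w.r.t. the CA atoms
planted_spec <- function(n_res = 10L, lambdas = c(1.0, 0.25),
                         noise_sigma = 0.1, atoms_per_residue = 3L) {
  st <- synthetic_structure(n_res, atoms_per_residue)
  ca <- select_atoms(st, "calpha")
  profs <- list(sin(seq(0, pi, length.out = n_res)),
                cos(seq(0, 2 * pi, length.out = n_res)),
                sin(seq(0, 3 * pi, length.out = n_res)))
  dirs <- list(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  k <- length(lambdas)
  m <- do.call(cbind, lapply(seq_len(k), function(i)
    plant_mode(st, profs[[i]], dirs[[i]])))
  m <- orthonormalize_modes(project_out_rigid_body(m, st$reference_coords, ca))
  gaussian_ensemble_spec(st, m, lambdas, noise_sigma = noise_sigma)
}

# squared-exponential correlated chain over `chain_res`; strictly
# sub-multiplicative correlations, so the chain is the unique optimal path
chain_spec <- function(n_res = 10L, chain_res = 1:6, adj_corr = 0.9,
                       noise_sigma = 0.05) {
  st <- synthetic_structure(n_res)
  ell2 <- -1 / log(adj_corr)
  K <- outer(chain_res, chain_res, function(i, j) exp(-(i - j)^2 / ell2))
  eg <- eigen(K, symmetric = TRUE)
  keep <- eg$values > 1e-10
  modes <- do.call(cbind, lapply(which(keep), function(q) {
    w <- numeric(n_res); w[chain_res] <- eg$vectors[, q]
    plant_mode(st, w, c(1, 0, 0))
  }))
  lam <- eg$values[keep]
  ord <- order(lam, decreasing = TRUE)
  gaussian_ensemble_spec(st, modes[, ord, drop = FALSE], lam[ord],
                         noise_sigma = noise_sigma)
}

# well-separated conformer mixture: conformers differ by an internal hinge
# rotation of the second half of the chain (translations would be removed
# by superposition), separation >> jitter
separable_mixture <- function(n_res = 8L, m = 2L, weights = NULL,
                              jitter = 0.1, separation = NULL) {
  st <- synthetic_structure(n_res)
  if (is.null(weights)) weights <- rep(1 / m, m)
  ref <- st$reference_coords
  moving <- which(st$atoms$res_index > n_res / 2)
  hinge <- ref[min(moving), ]
  confs <- lapply(seq_len(m), function(i) {
    th <- (i - 1) * 2 * pi / (m + 1)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    out <- ref
    out[moving, ] <- sweep(sweep(ref[moving, , drop = FALSE], 2, hinge) %*% R,
                           2, hinge, "+")
    out
  })
  conformer_mixture_spec(st, confs, weights, jitter_sigma = jitter)
}

# hand-written two-residue PDB text (one GLY with hydrogens + one HETATM
# ligand) used by the reader tests
toy_pdb_lines <- function() {
  c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.300   2.400   0.000  1.00  0.00           O",
    "ATOM      5  H   GLY A   1      -0.500  -0.800   0.000  1.00  0.00           H",
    "ATOM      6  N   GLY A   2       3.300   1.500   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       4.000   2.800   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.500   2.600   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.100   1.500   0.000  1.00  0.00           O",
    "HETATM   10  C1  LIG A  90       8.000   0.000   0.000  1.00  0.00           C",
    "HETATM   11  O1  LIG A  90       8.000   1.200   0.000  1.00  0.00           O",
    "END")
}
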