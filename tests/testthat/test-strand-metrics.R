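test_that("a point-mass psi lands in a single left-closed bin", {
  ens <- make_dihedral_ensemble(matrix(140, 37, 2))
  h <- psi_histogram(ens, 1, bin_width = 10)
  expect_equal(sum(h$counts), 37)
  hot <- which(h$counts > 0)
  expect_length(hot, 1)
  expect_equal(h$bin_edges[hot], 140)       # bin [140, 150)
  expect_equal(h$counts[hot], 37)
  expect_equal(h$density[hot], 1 / 10)
})

test_that("histogram counts partition the frames for every residue", {
  sp <- study_peptides()[["3b"]]
  bm <- basin_model(beta_weight = c(0.5, 0.633, 0.594, 0.747, 0.5))
  ens <- sample_dihedrals(sp, bm, 777, seed = 2)
  for (i in 1:5)
    expect_equal(sum(psi_histogram(ens, i)$counts), 777)
  expect_error(psi_histogram(ens, 1, bin_width = 7), "divisor")
})

test_that("uniform psi gives near-uniform bin probabilities", {
  set.seed(60)
  n <- 20000
  psi <- matrix(stats::runif(2 * n, -180, 180), n, 2)
  ens <- make_dihedral_ensemble(psi)
  h <- psi_histogram(ens, 1, bin_width = 30)
  p <- h$counts / h$n_total
  p0 <- 1 / length(p)
  expect_lt(max(abs(p - p0)), 5 * sqrt(p0 * (1 - p0) / n))
})

test_that("basin probabilities match analytic measures", {
  # point mass inside the beta window
  ens <- make_dihedral_ensemble(matrix(140, 10, 2))
  expect_equal(basin_probability(ens, 1, basin_window("beta")), 1.0)
  # uniform psi: window widths over 360
  set.seed(61)
  n <- 50000
  unif <- make_dihedral_ensemble(matrix(stats::runif(2 * n, -180, 180), n, 2))
  expect_equal(basin_probability(unif, 1, basin_window("beta")),
               90 / 360, tolerance = 0.02)
  expect_equal(basin_probability(unif, 1, basin_window("alpha")),
               110 / 360, tolerance = 0.02)
  # boundary values count inward
  edge <- make_dihedral_ensemble(matrix(c(90, 180, 89.999, 180.0), 4, 2))
  expect_equal(basin_probability(edge, 1), 3 / 4)
})

test_that("sampled basin probability recovers the analytic mixture mass", {
  sp <- peptide_spec(c("VAL", "TFS", "VAL"))
  bm <- basin_model(beta_weight = c(0.5, 0.827, 0.5), beta_sd = 15,
                    alpha_sd = 15)
  ens <- sample_dihedrals(sp, bm, 50000, seed = 71)
  p_hat <- basin_probability(ens, 2, basin_window("beta"))
  p_true <- oracle_mixture_mass(0.827, 140, 15, -30, 15)
  expect_lt(abs(p_hat - p_true), 0.01)
})

test_that("the extension probability is the product of its inputs", {
  expect_equal(100 * global_extension_probability(c(0.779, 0.856, 0.748)),
               49.9, tolerance = 0.15)
  expect_equal(100 * global_extension_probability(c(0.599, 0.514, 0.558)),
               17.2, tolerance = 0.15)
  expect_identical(global_extension_probability(c(0.9, 0, 0.8)), 0)
  expect_equal(global_extension_probability(c(0.2, 0.7, 0.5)),
               global_extension_probability(c(0.7, 0.5, 0.2)))
  expect_error(global_extension_probability(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(global_extension_probability(numeric()), "empty")
})

test_that("the global probability never exceeds any per-residue probability", {
  set.seed(9)
  for (k in 1:25) {
    p <- stats::runif(sample(2:6, 1))
    expect_lte(global_extension_probability(p), min(p))
  }
})

test_that("disjoint alpha and beta windows carry at most unit total mass", {
  sp <- peptide_spec(c("ALA", "VAL"))
  for (w in c(0.1, 0.5, 0.9)) {
    bm <- basin_model(beta_weight = w, alpha_sd = 40, beta_sd = 40,
                      n_residues = 2)
    ens <- sample_dihedrals(sp, bm, 5000, seed = 80 + round(10 * w))
    tot <- basin_probability(ens, 1, basin_window("beta")) +
      basin_probability(ens, 1, basin_window("alpha"))
    expect_lte(tot, 1)
  }
})

test_that("end-to-end distance is Euclidean and isometry invariant", {
  # hand-built two-residue model: N1 at origin, C2 at (3, 4, 0)
  fake <- structure(list(
    xyz = matrix(c(0, 0, 0, 1, 1, 0, 3, 4, 0), 1),
    atoms = data.frame(name = c("N", "CA", "C"), resno = c(1L, 2L, 2L),
                       resid = c("ALA", "VAL", "VAL")),
    spec = NULL, geometry = NULL), class = "ensemble_3d")
  expect_equal(end_to_end_distances(fake)$distances, 5.0)

  xyz <- small_ensemble_3d(n = 5, seed = 31)
  d0 <- end_to_end_distances(xyz)$distances
  set.seed(13)
  rot <- random_rotation()
  moved <- xyz
  for (m in seq_len(nrow(xyz$xyz))) {
    coords <- matrix(xyz$xyz[m, ], ncol = 3, byrow = TRUE)
    moved$xyz[m, ] <- as.vector(t(coords %*% rot +
                                    matrix(c(5, -3, 11), nrow(coords), 3,
                                           byrow = TRUE)))
  }
  expect_equal(end_to_end_distances(moved)$distances, d0, tolerance = 1e-9)
  h <- end_to_end_distances(xyz)
  expect_equal(sum(h$prob), 1)
  expect_error(end_to_end_distances(fake$atoms), "ensemble_3d")
})

test_that("mean end-to-end distance grows with shared beta weight", {
  sp <- study_peptides()[["2a"]]
  means <- vapply(c(0.2, 0.5, 0.8), function(w) {
    bm <- basin_model(beta_weight = w, n_residues = 5)
    ens <- sample_dihedrals(sp, bm, 5000, seed = 55)
    mean(end_to_end_distances(build_coordinates(ens))$distances)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("propensity reports multiply their own per-residue values", {
  sp <- study_peptides()[["4b"]]
  bm <- basin_model(beta_weight = c(0.6, 0.779, 0.856, 0.748, 0.6))
  ens <- sample_dihedrals(sp, bm, 2000, seed = 19)
  rep <- propensity_report(ens)
  expect_identical(rep$residues, 2:4)
  expect_equal(rep$p_global, prod(rep$p_beta))
  expect_true(all(rep$p_beta >= 0 & rep$p_beta <= 1))
})
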