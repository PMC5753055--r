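test_that("kabsch superposition handles identity and isometries", {
  set.seed(1)
  a <- matrix(stats::rnorm(15), 5, 3)
  id <- kabsch_superpose(a, a)
  expect_equal(id$rmsd_nm, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  rot <- random_rotation()
  b <- a %*% rot + matrix(c(1, -2, 3), 5, 3, byrow = TRUE)
  fit <- kabsch_superpose(a, b)
  expect_lte(fit$rmsd_nm, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(a, b[1:4, ]), "matched")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("kabsch RMSD beats a brute-force random-rotation search", {
  set.seed(2)
  for (rep in 1:3) {
    a <- matrix(stats::rnorm(15), 5, 3)
    b <- matrix(stats::rnorm(15), 5, 3)
    r_kabsch <- kabsch_superpose(a, b)$rmsd_ang
    r_random <- min(vapply(1:1000, function(i)
      rmsd_under_rotation(a, b, random_rotation()), numeric(1)))
    expect_lte(r_kabsch, r_random + 1e-12)
  }
})

test_that("kabsch RMSD agrees with an independent reference implementation", {
  xyz <- small_ensemble_3d(n = 4, seed = 77)
  sel <- select_atoms(xyz)
  for (pair in list(c(1, 2), c(2, 4), c(3, 4))) {
    mine <- kabsch_superpose(
      matrix(xyz$xyz[pair[1], rep(3 * sel, each = 3) - 2:0], ncol = 3,
             byrow = TRUE),
      matrix(xyz$xyz[pair[2], rep(3 * sel, each = 3) - 2:0], ncol = 3,
             byrow = TRUE))$rmsd_ang
    idx <- as.vector(vapply(sel, function(k) (3 * k - 2):(3 * k),
                            numeric(3)))
    ref <- bio3d::rmsd(xyz$xyz[pair[1], idx], xyz$xyz[pair[2], idx],
                       fit = TRUE)
    expect_equal(mine, ref, tolerance = 1e-3)
  }
})

test_that("pairwise RMSD matrices are symmetric, zero-diagonal and self-consistent", {
  xyz <- small_ensemble_3d(n = 6, seed = 23)
  m <- pairwise_rmsd(xyz)
  expect_identical(unclass(m), t(unclass(m)))
  expect_equal(diag(m), rep(0, 6))
  expect_true(all(m >= 0))
  # duplicated models: all-zero matrix
  dup <- xyz
  dup$xyz <- xyz$xyz[rep(1, 4), , drop = FALSE]
  expect_lte(max(pairwise_rmsd(dup)), 1e-12)
  # spot-check entries against single-pair superposition
  sel <- select_atoms(xyz)
  for (pair in list(c(1, 4), c(2, 6), c(3, 5))) {
    one <- kabsch_superpose(
      matrix(xyz$xyz[pair[1], as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))],
             ncol = 3, byrow = TRUE),
      matrix(xyz$xyz[pair[2], as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))],
             ncol = 3, byrow = TRUE))$rmsd_nm
    expect_equal(m[pair[1], pair[2]], one, tolerance = 1e-12)
  }
})

test_that("daura clustering handles the degenerate regimes", {
  n <- 7
  near <- matrix(0.01, n, n); diag(near) <- 0
  res <- daura_cluster(near, cutoff = 0.2)
  expect_length(res$clusters, 1)
  expect_equal(sort(res$clusters[[1]]), 1:n)
  expect_equal(res$centers, 1L)            # tie resolved to lowest index
  far <- matrix(5, n, n); diag(far) <- 0
  res2 <- daura_cluster(far, cutoff = 0.2)
  expect_length(res2$clusters, n)
  expect_true(all(lengths(res2$clusters) == 1))
})

test_that("two 3-cliques separate into exactly two clusters", {
  m <- matrix(1, 6, 6)
  m[1:3, 1:3] <- 0.05; m[4:6, 4:6] <- 0.05
  diag(m) <- 0
  res <- daura_cluster(m, cutoff = 0.2)
  expect_length(res$clusters, 2)
  expect_equal(sort(res$clusters[[1]]), 1:3)
  expect_equal(sort(res$clusters[[2]]), 4:6)
  oracle <- oracle_daura(m, 0.2)
  expect_identical(res$clusters, oracle$clusters)
  expect_identical(res$centers, oracle$centers)
})

test_that("daura clustering equals the brute-force greedy oracle", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    x <- matrix(stats::runif(n * n, 0, 0.5), n, n)
    m <- (x + t(x)) / 2
    diag(m) <- 0
    for (cutoff in c(0.1, 0.25, 0.4)) {
      res <- daura_cluster(m, cutoff)
      oracle <- oracle_daura(m, cutoff)
      expect_identical(res$clusters, oracle$clusters)
      expect_identical(res$centers, oracle$centers)
      # partition invariant
      expect_identical(sort(unlist(res$clusters)), 1:n)
      # first cluster at least as large as any other
      expect_true(all(lengths(res$clusters) <= length(res$clusters[[1]])))
      # sizes non-increasing in extraction order
      expect_true(all(diff(lengths(res$clusters)) <= 0))
    }
  }
})

test_that("cluster count is non-increasing in the cutoff", {
  set.seed(7)
  n <- 12
  x <- matrix(stats::runif(n * n, 0, 0.6), n, n)
  m <- (x + t(x)) / 2; diag(m) <- 0
  counts <- vapply(c(0.05, 0.15, 0.3, 0.5, 0.7), function(cut)
    length(daura_cluster(m, cut)$clusters), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster_ensemble partitions real conformers at 0.2 nm", {
  xyz <- small_ensemble_3d(n = 20, seed = 3,
                           beta_weight = c(0.5, 0.5, 0.5, 0.5, 0.5))
  res <- cluster_ensemble(xyz, cutoff = 0.2)
  expect_identical(sort(unlist(res$clusters)), 1:20)
  expect_true(all(vapply(seq_along(res$clusters), function(k)
    res$centers[k] %in% res$clusters[[k]], logical(1))))
})
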