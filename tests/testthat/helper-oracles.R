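# Independent oracles and small fixture builders used across the suite.

# Mass of a wrapped-Gaussian mixture inside [lo, hi], by numerical
# integration of the wrapped density (independent of basin_mass, which is
# closed-form over periodic images).
oracle_mixture_mass <- function(weight, beta_center, beta_sd,
                                alpha_center, alpha_sd, lo = 90, hi = 180) {
  dens <- function(x) {
    k <- -3:3
    vapply(x, function(xi) {
      db <- sum(stats::dnorm(xi + 360 * k, beta_center, beta_sd))
      da <- sum(stats::dnorm(xi + 360 * k, alpha_center, alpha_sd))
      weight * db + (1 - weight) * da
    }, numeric(1))
  }
  stats::integrate(dens, lo, hi, rel.tol = 1e-10)$value
}

# Dihedral of four points by an independent route: angle between plane
# normals from acos, sign from the scalar triple product.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  ang <- acos(max(-1, min(1, sum(n1 * n2) /
                            sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
  if (sum(n1 * b3) < 0) ang <- -ang
  ang
}

# Uniform random proper rotation matrix (QR of a Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# RMSD of b onto a after centroid alignment under a *given* rotation.
rmsd_under_rotation <- function(a, b, rot) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b)) %*% rot
  sqrt(mean(rowSums((b0 - a0)^2)))
}

# Independent transcription of the greedy neighbor-count clustering:
# explicit loops, no shared code with daura_cluster.
oracle_daura <- function(m, cutoff) {
  n <- nrow(m)
  left <- seq_len(n)
  clusters <- list(); centers <- integer()
  while (length(left) > 0) {
    best <- -1L; best_i <- NA_integer_
    for (i in left) {
      cnt <- 0L
      for (j in left) if (m[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; best_i <- i }  # first max = lowest index
    }
    memb <- integer()
    for (j in left) if (m[best_i, j] <= cutoff) memb <- c(memb, j)
    clusters[[length(clusters) + 1L]] <- memb
    centers <- c(centers, best_i)
    left <- setdiff(left, memb)
  }
  list(clusters = clusters, centers = centers)
}

# Build a dihedral_ensemble directly from matrices (frames x residues).
make_dihedral_ensemble <- function(psi, phi = NULL,
                                   sequence = NULL, n_terminus = "boc") {
  psi <- as.matrix(psi)
  nf <- nrow(psi); nr <- ncol(psi)
  if (is.null(sequence))
    sequence <- rep(c("ALA", "VAL", "THR", "VAL", "LEU"), length.out = nr)
  if (is.null(phi)) phi <- matrix(-120, nf, nr)
  spec <- peptide_spec(sequence, n_terminus = n_terminus)
  structure(list(n_frames = nf, spec = spec, seed = NA_integer_,
                 phi = as.matrix(phi), psi = psi,
                 omega = matrix(180, nf, nr), chi1 = matrix(60, nf, nr)),
            class = "dihedral_ensemble")
}

# Shared tiny study ensemble for coordinate/clustering tests.
small_ensemble_3d <- function(n = 8, seed = 42, label = "4a",
                              beta_weight = c(0.6, 0.671, 0.827, 0.756, 0.6)) {
  sp <- study_peptides()[[label]]
  bm <- basin_model(beta_weight = beta_weight)
  build_coordinates(sample_dihedrals(sp, bm, n, seed))
}
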