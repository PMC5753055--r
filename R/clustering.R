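#' Atom selection for superposition
#'
#' Selects the atom rows of an `ensemble_3d` used for RMSD. The default
#' selects backbone heavy atoms (N, CA, C, O) of the peptide residues
#' (residue numbers >= 1, excluding cap and ester atoms).
#'
#' @param ensemble An `ensemble_3d`.
#' @param names Atom names to keep.
#' @param residues Residue numbers to keep (default: all residues >= 1).
#' @return Integer vector of selected atom indices (rows of
#'   `ensemble$atoms`).
#' @export
select_atoms <- function(ensemble, names = c("N", "CA", "C", "O"),
                         residues = NULL) {
  at <- ensemble$atoms
  keep <- at$name %in% names & at$resno >= 1L & at$resid != "OME"
  if (!is.null(residues)) keep <- keep & at$resno %in% residues
  which(keep)
}

# n x 3 coordinate matrix of one model restricted to selected atoms
model_coords <- function(ensemble, model, sel) {
  idx <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  matrix(ensemble$xyz[model, idx], ncol = 3, byrow = TRUE)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body superposition of two coordinate sets by the
#' Kabsch algorithm: both sets are centered, the rotation is obtained from
#' the SVD of the covariance matrix with a sign correction that guarantees a
#' proper rotation (determinant +1, no reflection), and the residual RMSD is
#' minimal over all rigid transforms.
#'
#' @param a,b Numeric `n x 3` coordinate matrices (Angstrom), `n >= 3`,
#'   matched row by row; `b` is superposed onto `a`.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3; the
#'   transform is `b %*% rotation + translation`), `rmsd_nm` and `rmsd_ang`.
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    stop("coordinate sets must be matched n x 3 matrices")
  if (nrow(a) < 3L) stop("need at least 3 atoms for superposition")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (svd_degenerate(a0) || svd_degenerate(b0))
    stop("degenerate (collinear) atom selection")
  h <- crossprod(b0, a0)                 # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- b0 %*% rot
  rmsd <- sqrt(mean(rowSums((fit - a0)^2)))
  list(rotation = rot, translation = ca - cb %*% rot,
       rmsd_ang = rmsd, rmsd_nm = rmsd / 10)
}

svd_degenerate <- function(x) {
  sv <- svd(x, nu = 0, nv = 0)$d
  sv[2] < 1e-8 * max(sv[1], 1e-12)
}

#' Pairwise RMSD matrix of an ensemble
#'
#' All-against-all Kabsch RMSD over the selected atoms.
#'
#' @param ensemble An `ensemble_3d` with >= 2 models.
#' @param selection Atom indices from [select_atoms()] (default: backbone
#'   heavy atoms).
#' @return Object of class `"rmsd_matrix"`: symmetric `n x n` matrix in nm
#'   with zero diagonal.
#' @export
pairwise_rmsd <- function(ensemble, selection = select_atoms(ensemble)) {
  nf <- nrow(ensemble$xyz)
  if (nf < 2L) stop("need at least 2 models")
  coords <- lapply(seq_len(nf), model_coords, ensemble = ensemble,
                   sel = selection)
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in seq((i + 1L), nf)) {
      m[i, j] <- m[j, i] <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd_nm
    }
  }
  structure(m, class = c("rmsd_matrix", class(m)))
}

#' Neighbor-count ("gromos"/Daura) clustering
#'
#' Greedy clustering of conformers from a pairwise RMSD matrix: the frame
#' with the most neighbors within `cutoff` becomes the center of the first
#' cluster, that cluster (center plus its unassigned neighbors) is removed,
#' and the procedure repeats on the remainder until every frame is assigned.
#' Ties in neighbor count are broken by the lowest frame index.
#'
#' @param matrix An `n x n` symmetric RMSD matrix (nm), e.g. from
#'   [pairwise_rmsd()].
#' @param cutoff Neighbor cutoff in nm (default 0.2 nm, the standard
#'   threshold for peptide backbone clustering).
#' @return Object of class `"cluster_result"`: list with `clusters` (list of
#'   member index vectors, sizes non-increasing), `centers` (one
#'   representative frame per cluster), `assignment` (cluster id per frame)
#'   and `cutoff`.
#' @export
daura_cluster <- function(matrix, cutoff = 0.2) {
  m <- unclass(matrix)
  n <- nrow(m)
  if (is.null(n) || n != ncol(m)) stop("RMSD matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) stop("RMSD matrix must be symmetric")
  if (cutoff <= 0) stop("cutoff must be > 0")
  unassigned <- rep(TRUE, n)
  clusters <- list(); centers <- integer()
  assignment <- integer(n)
  while (any(unassigned)) {
    idx <- which(unassigned)
    nb <- vapply(idx, function(i) sum(m[i, idx] <= cutoff), numeric(1))
    center <- idx[which.max(nb)]          # which.max: lowest index on ties
    members <- idx[m[center, idx] <= cutoff]
    k <- length(clusters) + 1L
    clusters[[k]] <- members
    centers[k] <- center
    assignment[members] <- k
    unassigned[members] <- FALSE
  }
  # extraction order already has non-increasing sizes: each step maximizes
  # the neighbor count over a subset of the previous step's frames
  structure(list(clusters = clusters, centers = centers,
                 assignment = assignment, cutoff = cutoff,
                 n_frames = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Daura clustering at ", x$cutoff, " nm: ", length(x$clusters),
      " clusters over ", x$n_frames, " frames; sizes ",
      paste(utils::head(lengths(x$clusters), 5), collapse = ", "),
      if (length(x$clusters) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Cluster an ensemble end to end
#'
#' Convenience wrapper: pairwise backbone RMSD then [daura_cluster()].
#'
#' @inheritParams pairwise_rmsd
#' @inheritParams daura_cluster
#' @return A `cluster_result`.
#' @export
cluster_ensemble <- function(ensemble, cutoff = 0.2,
                             selection = select_atoms(ensemble)) {
  daura_cluster(pairwise_rmsd(ensemble, selection), cutoff)
}
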