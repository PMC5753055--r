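#' Ramachandran basin window
#'
#' Inclusive psi-angle window defining a conformational basin. The defaults
#' are the alpha region \[-70, +40\] degrees and the beta (extended) basin
#' \[+90, +180\] degrees; an angle exactly at a boundary counts inside.
#'
#' @param label `"alpha"`, `"beta"`, or `"custom"`.
#' @param lo,hi Window bounds in degrees (`lo < hi`); required for
#'   `"custom"`, otherwise defaulted from the label.
#' @return Object of class `"basin_window"`.
#' @export
basin_window <- function(label = c("beta", "alpha", "custom"),
                         lo = NULL, hi = NULL) {
  label <- match.arg(label)
  if (label == "beta")  { if (is.null(lo)) lo <- 90;  if (is.null(hi)) hi <- 180 }
  if (label == "alpha") { if (is.null(lo)) lo <- -70; if (is.null(hi)) hi <- 40 }
  if (is.null(lo) || is.null(hi)) stop("custom window needs lo and hi")
  if (!(lo < hi)) stop("window requires lo < hi")
  structure(list(label = label, lo = lo, hi = hi), class = "basin_window")
}

#' Histogram of psi for one residue
#'
#' Bins the psi angles of one residue over all frames. Bins are left-closed
#' right-open (\code{[lo, hi)}) except the last, which is closed at +180 so
#' that the whole wrapped domain (-180, 180] is covered; `bin_width` must
#' divide 360 exactly.
#'
#' @param ensemble A `dihedral_ensemble`.
#' @param residue_index Residue whose psi is binned.
#' @param bin_width Bin width in degrees (default 5).
#' @return Object of class `"psi_histogram"`: list with `residue_index`,
#'   `bin_edges`, `counts`, `n_total` and `density` (probability per
#'   degree: counts / (n_total * bin_width)).
#' @export
psi_histogram <- function(ensemble, residue_index, bin_width = 5) {
  stopifnot(inherits(ensemble, "dihedral_ensemble"))
  if (!isTRUE(all.equal(360 %% bin_width, 0)) || bin_width <= 0)
    stop("bin_width must be a positive divisor of 360 degrees")
  psi <- residue_psi(ensemble, residue_index)
  edges <- seq(-180, 180, by = bin_width)
  bin <- findInterval(psi, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  structure(list(residue_index = residue_index, bin_edges = edges,
                 counts = counts, n_total = length(psi),
                 density = counts / (length(psi) * bin_width)),
            class = "psi_histogram")
}

residue_psi <- function(ensemble, residue_index) {
  n_res <- ncol(ensemble$psi)
  if (residue_index < 1L || residue_index > n_res)
    stop("residue_index out of range")
  psi <- ensemble$psi[, residue_index]
  if (anyNA(psi))
    stop("psi undefined for residue ", residue_index)
  psi
}

#' Basin occupation probability
#'
#' Fraction of frames whose psi for one residue lies inside the window
#' (both bounds inclusive). When the window bounds align with histogram bin
#' edges this equals the integral of the normalized psi histogram over the
#' window.
#'
#' @inheritParams psi_histogram
#' @param window A [basin_window()].
#' @return Probability in \[0, 1\].
#' @examples
#' sp <- study_peptides()[["4b"]]
#' ens <- sample_dihedrals(sp, basin_model(beta_weight = 0.8, n_residues = 5),
#'                         n_frames = 1000, seed = 1)
#' basin_probability(ens, 3, basin_window("beta"))
#' @export
basin_probability <- function(ensemble, residue_index,
                              window = basin_window("beta")) {
  stopifnot(inherits(window, "basin_window"))
  psi <- residue_psi(ensemble, residue_index)
  mean(psi >= window$lo & psi <= window$hi)
}

#' Global extension probability
#'
#' Probability that all listed residues are simultaneously in the beta
#' basin, computed as the product of their individual beta probabilities
#' (independence across residues, as when each probability is a marginal of
#' an ensemble with independently sampled residues).
#'
#' @param p_list Numeric vector of per-residue probabilities, each in
#'   \[0, 1\].
#' @return The product, a probability in \[0, 1\].
#' @examples
#' global_extension_probability(c(0.779, 0.856, 0.748))  # ~0.499
#' @export
global_extension_probability <- function(p_list) {
  p <- as.numeric(unlist(p_list))
  if (!length(p)) stop("p_list is empty")
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")
  prod(p)
}

#' Per-peptide beta-propensity report
#'
#' Computes the per-residue beta-basin probabilities for the selected
#' residues of an ensemble and their product, the global extension
#' probability.
#'
#' @param ensemble A `dihedral_ensemble`.
#' @param residues Residue indices to report (default: the central three of
#'   a pentapeptide, 2:4).
#' @param window Beta [basin_window()].
#' @return Object of class `"propensity_report"`: list with `label`,
#'   `residues`, `p_beta` (named vector) and `p_global`.
#' @export
propensity_report <- function(ensemble, residues = 2:4,
                              window = basin_window("beta")) {
  p <- vapply(residues, function(i) basin_probability(ensemble, i, window),
              numeric(1))
  names(p) <- paste0(ensemble$spec$sequence[residues], residues)
  structure(list(label = ensemble$spec$label, residues = residues,
                 p_beta = p, p_global = global_extension_probability(p)),
            class = "propensity_report")
}

#' @export
print.propensity_report <- function(x, ...) {
  cat("Peptide ", x$label, ": p_beta = ",
      paste(sprintf("%s %.1f%%", names(x$p_beta), 100 * x$p_beta),
            collapse = ", "),
      "; P = ", sprintf("%.1f%%", 100 * x$p_global), "\n", sep = "")
  invisible(x)
}

#' End-to-end distance distribution
#'
#' Per-model distance between the N-terminal backbone nitrogen (N of residue
#' 1) and the C-terminal carbonyl carbon (C of the last residue, the methyl
#' ester carbonyl). Large values indicate globally extended conformations.
#'
#' @param ensemble An `ensemble_3d`.
#' @param bin_width Histogram bin width in Angstrom.
#' @return Object of class `"end_to_end_result"`: list with `distances`
#'   (Angstrom, one per model), `breaks`, `prob` (histogram mass summing to
#'   1) and the atom pair definition.
#' @export
end_to_end_distances <- function(ensemble, bin_width = 0.5) {
  stopifnot(inherits(ensemble, "ensemble_3d"))
  n_res <- max(ensemble$atoms$resno[ensemble$atoms$name == "C"])
  a <- atom_xyz(ensemble, "N", 1L)
  b <- atom_xyz(ensemble, "C", n_res)
  d <- sqrt(rowSums((a - b)^2))
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(distances = d, breaks = h$breaks,
                 prob = h$counts / length(d),
                 atom_pair = c(from = "N of residue 1",
                               to = sprintf("C of residue %d (ester carbonyl)",
                                            n_res))),
            class = "end_to_end_result")
}
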