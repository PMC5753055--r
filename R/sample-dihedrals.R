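#' Sample a backbone dihedral ensemble
#'
#' Draws `n_frames` independent conformations of the peptide described by
#' `spec` from the two-basin mixture `model`. For every frame and residue,
#' psi comes from the wrapped-Gaussian alpha/beta mixture (component chosen
#' with probability `beta_weight`), phi from its own wrapped Gaussian, omega
#' is fixed trans (180 degrees), and chi1 is drawn from its Gaussian (or
#' emitted as a constant when `chi1_sd` is 0). Draws are independent across
#' frames and residues; all angles are wrapped into (-180, 180].
#'
#' The generator is fully determined by `(spec, model, n_frames, seed)`:
#' a single Mersenne-Twister stream is seeded with `seed` and consumed in a
#' fixed documented order (component indicators for all frames x residues,
#' then the psi deviates, then phi, then chi1; each block frame-major), so
#' identical inputs give bitwise-identical ensembles.
#'
#' @param spec A [peptide_spec()].
#' @param model A [basin_model()] with one row per residue of `spec`.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer RNG seed.
#' @return An object of class `"dihedral_ensemble"`: a list with `n_frames`,
#'   `spec`, `seed`, and `n_frames x n_residues` matrices `phi`, `psi`,
#'   `omega`, `chi1` (degrees in (-180, 180]).
#' @examples
#' sp <- study_peptides()[["4b"]]
#' bm <- basin_model(beta_weight = c(0.7, 0.779, 0.856, 0.748, 0.7))
#' ens <- sample_dihedrals(sp, bm, n_frames = 100, seed = 1)
#' @export
sample_dihedrals <- function(spec, model, n_frames, seed) {
  stopifnot(inherits(spec, "peptide_spec"))
  n_res <- length(spec$sequence)
  if (nrow(model) != n_res)
    stop("basin model has ", nrow(model), " residues but peptide has ", n_res)
  validate_basin_model(model)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("n_frames must be >= 1")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")

  w <- matrix(rep(model$beta_weight, each = n_frames), n_frames, n_res)
  use_beta <- matrix(stats::runif(n_frames * n_res), n_frames, n_res) < w
  z_psi <- matrix(stats::rnorm(n_frames * n_res), n_frames, n_res)
  z_phi <- matrix(stats::rnorm(n_frames * n_res), n_frames, n_res)
  z_chi <- matrix(stats::rnorm(n_frames * n_res), n_frames, n_res)

  center <- ifelse(use_beta,
                   rep(model$beta_center, each = n_frames),
                   rep(model$alpha_center, each = n_frames))
  sd     <- ifelse(use_beta,
                   rep(model$beta_sd, each = n_frames),
                   rep(model$alpha_sd, each = n_frames))
  psi <- wrap_angle(center + sd * z_psi)
  phi <- wrap_angle(matrix(rep(model$phi_center, each = n_frames), n_frames) +
                    matrix(rep(model$phi_sd, each = n_frames), n_frames) * z_phi)
  chi <- wrap_angle(matrix(rep(model$chi1_center, each = n_frames), n_frames) +
                    matrix(rep(model$chi1_sd, each = n_frames), n_frames) * z_chi)
  omega <- matrix(180, n_frames, n_res)

  dn <- list(NULL, spec$sequence)
  dimnames(psi) <- dimnames(phi) <- dimnames(chi) <- dimnames(omega) <- dn
  structure(
    list(n_frames = n_frames, spec = spec, seed = as.integer(seed),
         phi = phi, psi = psi, omega = omega, chi1 = chi),
    class = "dihedral_ensemble")
}

#' @export
print.dihedral_ensemble <- function(x, ...) {
  cat("Dihedral ensemble: ", x$n_frames, " frames x ",
      length(x$spec$sequence), " residues (", x$spec$label, "), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read a dihedral ensemble as CSV
#'
#' Long-format serialization with columns `frame`, `residue_index`,
#' `residue_code`, `phi`, `psi`, `omega`, `chi1` (degrees).
#'
#' @param ensemble A `dihedral_ensemble`.
#' @param path File path.
#' @return `write_dihedral_csv()` returns `path` invisibly;
#'   `read_dihedral_csv()` returns a `dihedral_ensemble` (with a
#'   reconstructed `peptide_spec`; terminal chemistry defaults to Boc unless
#'   given).
#' @export
write_dihedral_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "dihedral_ensemble"))
  n_res <- length(ensemble$spec$sequence)
  df <- data.frame(
    frame = rep(seq_len(ensemble$n_frames), times = n_res),
    residue_index = rep(seq_len(n_res), each = ensemble$n_frames),
    residue_code = rep(ensemble$spec$sequence, each = ensemble$n_frames),
    phi = as.vector(ensemble$phi), psi = as.vector(ensemble$psi),
    omega = as.vector(ensemble$omega), chi1 = as.vector(ensemble$chi1))
  df <- df[order(df$frame, df$residue_index), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dihedral_csv
#' @param n_terminus,c_terminus Terminal chemistry for the reconstructed
#'   [peptide_spec()].
#' @param label Peptide label for the reconstructed spec.
#' @export
read_dihedral_csv <- function(path, n_terminus = "boc",
                              c_terminus = "methyl-ester", label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "residue_index", "residue_code", "phi", "psi", "omega", "chi1")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dihedral CSV missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$frame, df$residue_index), ]
  frames <- sort(unique(df$frame))
  resi <- sort(unique(df$residue_index))
  if (nrow(df) != length(frames) * length(resi))
    stop("dihedral CSV is not a complete frame x residue grid")
  codes <- df$residue_code[match(resi, df$residue_index)]
  spec <- peptide_spec(codes, n_terminus = n_terminus,
                       c_terminus = c_terminus, label = label)
  shape <- function(v) {
    m <- matrix(v, nrow = length(frames), ncol = length(resi), byrow = TRUE)
    dimnames(m) <- list(NULL, spec$sequence)
    m
  }
  structure(
    list(n_frames = length(frames), spec = spec, seed = NA_integer_,
         phi = shape(df$phi), psi = shape(df$psi),
         omega = shape(df$omega), chi1 = shape(df$chi1)),
    class = "dihedral_ensemble")
}
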