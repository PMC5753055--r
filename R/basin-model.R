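#' Two-basin backbone sampling model
#'
#' Per-residue specification of a two-component wrapped-Gaussian mixture for
#' the backbone psi dihedral, plus a single Gaussian for phi. Each residue's
#' psi is drawn from the beta component (centered near +140 degrees, the
#' extended/beta-strand region) with probability `beta_weight` and otherwise
#' from the alpha component (centered near -30 degrees, the helical region).
#' The defaults mirror the peak centers seen in the psi distributions of
#' short Ala-Val-X-Val-Leu pentapeptide simulations; phi defaults to the
#' extended range (about -160 to -110 degrees).
#'
#' All parameters are recycled to the number of residues, so scalar inputs
#' describe a homogeneous chain.
#'
#' @param beta_weight Numeric in \[0, 1\], one per residue (or scalar):
#'   mixing proportion of the beta psi component.
#' @param beta_center,alpha_center Component centers, degrees.
#' @param beta_sd,alpha_sd Component standard deviations, degrees (> 0).
#'   Values are used as wrapped Gaussians: a draw is taken on the real line
#'   and wrapped into (-180, 180], which is accurate for sd <= 60 degrees.
#' @param phi_center,phi_sd Gaussian for phi, degrees.
#' @param chi1_center,chi1_sd Gaussian for the side-chain chi1 dihedral,
#'   degrees. The default is a fixed gauche+ rotamer (+60 degrees, sd 0:
#'   chi1 is emitted as a constant, not sampled).
#' @param n_residues Number of residues the model describes.
#' @return An object of class `"basin_model"`: a data frame with one row per
#'   residue.
#' @examples
#' basin_model(beta_weight = c(0.671, 0.827, 0.756), n_residues = 3)
#' @export
basin_model <- function(beta_weight = 0.5,
                        beta_center = 140, beta_sd = 15,
                        alpha_center = -30, alpha_sd = 15,
                        phi_center = -135, phi_sd = 15,
                        chi1_center = 60, chi1_sd = 0,
                        n_residues = max(length(beta_weight), 1L)) {
  n <- as.integer(n_residues)
  if (n < 1L) stop("n_residues must be >= 1")
  m <- data.frame(
    residue_index = seq_len(n),
    beta_weight   = rep_len(beta_weight, n),
    beta_center   = rep_len(beta_center, n),
    beta_sd       = rep_len(beta_sd, n),
    alpha_center  = rep_len(alpha_center, n),
    alpha_sd      = rep_len(alpha_sd, n),
    phi_center    = rep_len(phi_center, n),
    phi_sd        = rep_len(phi_sd, n),
    chi1_center   = rep_len(chi1_center, n),
    chi1_sd       = rep_len(chi1_sd, n))
  validate_basin_model(m)
  class(m) <- c("basin_model", "data.frame")
  m
}

validate_basin_model <- function(m) {
  bad <- which(!is.finite(m$beta_weight) | m$beta_weight < 0 | m$beta_weight > 1)
  if (length(bad))
    stop("beta_weight outside [0, 1] at residue ",
         paste(bad, collapse = ", "))
  if (any(m$beta_sd <= 0) || any(m$alpha_sd <= 0) || any(m$phi_sd <= 0))
    stop("basin standard deviations must be > 0")
  if (any(m$chi1_sd < 0)) stop("chi1_sd must be >= 0")
  invisible(m)
}

#' Analytic basin mass of a sampling model
#'
#' Probability that a psi angle drawn from the residue's two-component
#' wrapped-Gaussian mixture lies inside `window` (both bounds inclusive).
#' Computed in closed form by summing Gaussian probabilities over the
#' periodic images of the window, so it is the exact population the sampler
#' targets and the reference value against which empirically recovered basin
#' probabilities are compared.
#'
#' @param model A [basin_model()].
#' @param residue_index Residue whose psi mixture is integrated.
#' @param window A [basin_window()] (default: the beta basin, 90 to 180
#'   degrees).
#' @return Probability in \[0, 1\].
#' @export
basin_mass <- function(model, residue_index, window = basin_window("beta")) {
  r <- model[model$residue_index == residue_index, , drop = FALSE]
  if (nrow(r) != 1L) stop("residue_index not present in model")
  comp <- function(center, sd) {
    k <- -3:3   # periodic images; sd <= 60 deg makes further images negligible
    sum(stats::pnorm((window$hi + 360 * k - center) / sd) -
        stats::pnorm((window$lo + 360 * k - center) / sd))
  }
  r$beta_weight * comp(r$beta_center, r$beta_sd) +
    (1 - r$beta_weight) * comp(r$alpha_center, r$alpha_sd)
}
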