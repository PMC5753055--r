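#' Karplus parameter set for 3J(HN-HA)
#'
#' Coefficients of the Karplus relation
#' \deqn{{}^3J = A \cos^2\theta + B \cos\theta + C, \quad \theta = \phi + \mathrm{phase}}
#' relating the three-bond HN-HA scalar coupling to the backbone phi
#' dihedral. The default is a standard published HN-HA parameterization
#' (A = 6.51, B = -1.76, C = 1.60 Hz with theta = phi - 60 degrees); any
#' literature set can be supplied instead.
#'
#' @param A,B,C Coefficients in Hz.
#' @param phase Phase offset in degrees (theta = phi + phase).
#' @return Object of class `"karplus_parameters"`.
#' @export
karplus_parameters <- function(A = 6.51, B = -1.76, C = 1.60, phase = -60) {
  vals <- c(A = A, B = B, C = C, phase = phase)
  if (any(!is.finite(vals))) stop("Karplus parameters must be finite")
  structure(as.list(vals), class = "karplus_parameters")
}

#' Karplus back-calculation of 3J(HN-HA)
#'
#' Evaluates the Karplus relation at one or more phi angles.
#'
#' @param phi Backbone phi dihedral(s), degrees.
#' @param params A [karplus_parameters()] set.
#' @return Coupling constant(s) in Hz.
#' @examples
#' karplus_j(-120)  # extended phi: large coupling (9.87 Hz, default set)
#' @export
karplus_j <- function(phi, params = karplus_parameters()) {
  stopifnot(inherits(params, "karplus_parameters"))
  ct <- cos((phi + params$phase) * pi / 180)
  params$A * ct^2 + params$B * ct + params$C
}

#' Ensemble-averaged 3J(HN-HA)
#'
#' Arithmetic mean of the Karplus coupling over all frames of one residue:
#' the average of J over the ensemble, not J of the average phi.
#'
#' @param ensemble A `dihedral_ensemble`.
#' @param residue_index Residue whose phi is used.
#' @param params A [karplus_parameters()] set.
#' @return Mean coupling in Hz.
#' @export
ensemble_mean_j <- function(ensemble, residue_index,
                            params = karplus_parameters()) {
  stopifnot(inherits(ensemble, "dihedral_ensemble"))
  if (ensemble$n_frames < 1L) stop("empty ensemble")
  phi <- ensemble$phi[, residue_index]
  if (anyNA(phi)) stop("phi undefined for residue ", residue_index)
  mean(karplus_j(phi, params))
}

#' Coil-library reference couplings
#'
#' Mean random-coil 3J(HN-HA) values by residue. The default set carries the
#' three residues with published coil means used in this analysis:
#' Ala 6.1 Hz, Leu 7.0 Hz, Val 7.5 Hz. Residues absent from the set
#' (Ser, Thr and the CF3-threonines here) are treated as not comparable
#' rather than given invented values.
#'
#' @param values Named numeric vector, names being residue codes.
#' @return Object of class `"coil_library"` (named numeric vector).
#' @export
coil_library <- function(values = c(ALA = 6.1, LEU = 7.0, VAL = 7.5)) {
  if (is.null(names(values)) || any(names(values) == ""))
    stop("coil library values must be named by residue code")
  if (any(!is.finite(values) | values <= 0))
    stop("coil couplings must be positive and finite")
  structure(values, names = toupper(names(values)), class = "coil_library")
}

#' Compare observed couplings to the coil library
#'
#' For every entry of a long-format J table, computes
#' `delta = J_obs - J_coil` against the residue's coil-library mean and
#' flags entries with `delta > 0` as extended-leaning. Entries whose residue
#' has no coil reference are reported as not comparable; missing or
#' unresolvable measurements (markers in the table) propagate as missing and
#' are tallied in the QC attributes.
#'
#' @param jtable Data frame with columns `peptide`, `residue_index`,
#'   `residue_code`, `j_hz` (numeric, `NA` when not measured) and optionally
#'   `note` (e.g. `"broad"` for unresolvable peaks); see
#'   [jhnha_table()] for the shipped dataset in this layout.
#' @param coil A [coil_library()].
#' @return The input data frame with added columns `j_coil`, `delta`,
#'   `comparable` (logical) and `extended_flag` (logical, `NA` when not
#'   comparable), plus attributes `n_missing` and `n_unresolvable`.
#' @export
compare_to_coil <- function(jtable, coil = coil_library()) {
  stopifnot(inherits(coil, "coil_library"))
  need <- c("peptide", "residue_index", "residue_code", "j_hz")
  miss <- setdiff(need, names(jtable))
  if (length(miss))
    stop("jtable missing column(s): ", paste(miss, collapse = ", "))
  code <- toupper(jtable$residue_code)
  j_coil <- unname(unclass(coil)[code])
  delta <- jtable$j_hz - j_coil
  comparable <- !is.na(j_coil) & !is.na(jtable$j_hz)
  out <- jtable
  out$j_coil <- j_coil
  out$delta <- ifelse(comparable, delta, NA_real_)
  out$comparable <- comparable
  out$extended_flag <- ifelse(comparable, delta > 0, NA)
  note <- if ("note" %in% names(jtable)) jtable$note else rep("", nrow(jtable))
  attr(out, "n_missing") <- sum(is.na(jtable$j_hz) & note != "broad")
  attr(out, "n_unresolvable") <- sum(note == "broad", na.rm = TRUE)
  out
}
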