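#' Random-coil chemical shift reference
#'
#' Residue/nucleus random-coil shifts (ppm) used to compute chemical shift
#' deviations. The default set carries standard published coil values for
#' the natural residues of the Ala-Val-X-Val-Leu systems (HA and CA nuclei);
#' the CF3-threonine residues have no known random-coil values and are
#' deliberately absent, so they are reported as excluded rather than given
#' invented references.
#'
#' @param df Data frame with columns `residue_code`, `nucleus`, `shift_ppm`.
#' @param provenance Short label identifying the reference compilation.
#' @return Object of class `"coil_reference"`.
#' @export
coil_reference <- function(df = NULL, provenance = "wishart1995") {
  if (is.null(df)) {
    df <- data.frame(
      residue_code = rep(c("ALA", "VAL", "SER", "THR", "LEU"), 2),
      nucleus = rep(c("HA", "CA"), each = 5),
      shift_ppm = c(4.32, 4.12, 4.47, 4.35, 4.34,
                    52.5, 62.3, 58.3, 61.8, 55.1))
  }
  need <- c("residue_code", "nucleus", "shift_ppm")
  if (!all(need %in% names(df)))
    stop("coil reference needs columns: ", paste(need, collapse = ", "))
  df$residue_code <- toupper(df$residue_code)
  df$nucleus <- toupper(df$nucleus)
  structure(list(table = df, provenance = provenance),
            class = "coil_reference")
}

coil_lookup <- function(coil, residue_code, nucleus) {
  t <- coil$table
  i <- match(paste(toupper(residue_code), toupper(nucleus)),
             paste(t$residue_code, t$nucleus))
  t$shift_ppm[i]
}

#' Chemical shift deviations with exclusion rules
#'
#' CSD = observed shift minus the residue's random-coil reference, per
#' peptide, residue and nucleus at the reporting temperature. Two exclusion
#' rules are applied and recorded rather than silently dropped: terminal
#' residues (first and last of each peptide) are excluded because they lack
#' a neighboring residue on one side, and residues without a random-coil
#' reference (the CF3-threonines) are excluded as reference-less.
#'
#' @param shifts Data frame (shift table) with columns `peptide`,
#'   `residue_index`, `residue_code`, `nucleus`, `temperature_K`,
#'   `shift_ppm`.
#' @param coil A [coil_reference()].
#' @param temperature_K Reporting temperature (default 298 K).
#' @return Data frame with columns of `shifts` at the reporting temperature
#'   plus `csd_ppm` (`NA` when excluded) and `excluded` (`""`, `"terminal"`
#'   or `"no-reference"`).
#' @export
compute_csd <- function(shifts, coil = coil_reference(), temperature_K = 298) {
  need <- c("peptide", "residue_index", "residue_code", "nucleus",
            "temperature_K", "shift_ppm")
  miss <- setdiff(need, names(shifts))
  if (length(miss))
    stop("shift table missing column(s): ", paste(miss, collapse = ", "))
  s <- shifts[shifts$temperature_K == temperature_K, , drop = FALSE]
  if (!nrow(s)) stop("no shifts at the reporting temperature ", temperature_K, " K")
  s$excluded <- ""
  for (p in unique(s$peptide)) {
    rows <- s$peptide == p
    ri <- s$residue_index[rows]
    s$excluded[rows][ri == min(ri) | ri == max(ri)] <- "terminal"
  }
  ref <- coil_lookup(coil, s$residue_code, s$nucleus)
  s$excluded[is.na(ref) & s$excluded == ""] <- "no-reference"
  s$csd_ppm <- ifelse(s$excluded == "", s$shift_ppm - ref, NA_real_)
  s
}

#' Summarize a CSD selection
#'
#' Minimum, maximum and sign consistency over the included (non-excluded)
#' entries of a CSD table, typically restricted to specific residues
#' (e.g. the two valines of each pentapeptide).
#'
#' @param csd A CSD data frame: either the output of [compute_csd()]
#'   (column `csd_ppm`) or a transcribed fixture with a `csd_ppm` column.
#' @param residues Residue indices to include (default: all).
#' @return List with `min`, `max`, `n` and `sign_consistent` (`TRUE` when
#'   all included values share one sign).
#' @export
summarize_csd <- function(csd, residues = NULL) {
  v <- csd$csd_ppm
  keep <- !is.na(v)
  if ("excluded" %in% names(csd)) keep <- keep & csd$excluded == ""
  if (!is.null(residues)) keep <- keep & csd$residue_index %in% residues
  v <- v[keep]
  if (!length(v)) stop("no CSD entries left after exclusions")
  list(min = min(v), max = max(v), n = length(v),
       sign_consistent = all(v > 0) || all(v < 0))
}

#' Amide-proton temperature coefficient
#'
#' Ordinary least-squares slope of the amide proton chemical shift (ppm)
#' against temperature (K), scaled by 1000 to ppb/K.
#'
#' @param temperature_K Temperatures (K), at least 2 distinct values.
#' @param shift_ppm Chemical shifts (ppm), same length.
#' @return Object of class `"temp_coefficient"`: list with `slope_ppb_K`,
#'   `n_points` and `residual_sd` (ppm).
#' @examples
#' temp_coefficient(c(271, 285, 298), 8.5 - 0.0078 * (c(271, 285, 298) - 271))
#' @export
temp_coefficient <- function(temperature_K, shift_ppm) {
  if (length(temperature_K) != length(shift_ppm))
    stop("temperature and shift vectors must have equal length")
  ok <- is.finite(temperature_K) & is.finite(shift_ppm)
  temperature_K <- temperature_K[ok]; shift_ppm <- shift_ppm[ok]
  if (length(unique(temperature_K)) < 2L)
    stop("need shifts at >= 2 distinct temperatures")
  fit <- stats::lm(shift_ppm ~ temperature_K)
  structure(list(slope_ppb_K = 1000 * unname(stats::coef(fit)[2]),
                 n_points = length(shift_ppm),
                 residual_sd = sqrt(mean(stats::residuals(fit)^2))),
            class = "temp_coefficient")
}

#' Hydrogen-bond class from a temperature coefficient
#'
#' In protic solvents, weakly negative amide temperature coefficients
#' (slope > -4.5 ppb/K) usually indicate amide protons engaged in
#' intramolecular hydrogen bonds, while strongly negative values
#' (slope < -6 ppb/K) indicate solvent exposure. Values between the
#' thresholds, including the boundary values themselves (the defining
#' inequalities are strict), are classified intermediate.
#'
#' @param coef A `temp_coefficient` or a numeric slope in ppb/K.
#' @param hbond_threshold,exposed_threshold Class boundaries in ppb/K.
#' @return `"hbonded-candidate"`, `"intermediate"`, or `"exposed"`.
#' @examples
#' classify_hbond(-4.0)  # hbonded-candidate
#' classify_hbond(-7.8)  # exposed
#' @export
classify_hbond <- function(coef, hbond_threshold = -4.5,
                           exposed_threshold = -6) {
  slope <- if (inherits(coef, "temp_coefficient")) coef$slope_ppb_K else coef
  if (!is.finite(slope)) stop("slope must be finite")
  if (slope > hbond_threshold) "hbonded-candidate"
  else if (slope < exposed_threshold) "exposed"
  else "intermediate"
}

#' chi1 rotamer class from 3J(HA-HB)
#'
#' Small HA-HB couplings indicate a gauche relationship between the alpha
#' and beta protons (a dominant gauche rotamer); large couplings indicate a
#' dominant anti relationship; intermediate averages indicate a
#' conformational equilibrium between rotamers. Thresholds are the
#' conventional 5 and 10 Hz and are configurable; boundary values classify
#' as mixed.
#'
#' @param j Coupling constant in Hz (> 0).
#' @param gauche_max,anti_min Class boundaries in Hz.
#' @return `"gauche-dominated"`, `"mixed"`, or `"anti-dominated"`.
#' @examples
#' classify_chi1(2.5)  # gauche-dominated
#' classify_chi1(7.0)  # mixed
#' @export
classify_chi1 <- function(j, gauche_max = 5, anti_min = 10) {
  if (!is.finite(j) || j <= 0) stop("coupling must be a positive number")
  if (j < gauche_max) "gauche-dominated"
  else if (j > anti_min) "anti-dominated"
  else "mixed"
}

#' Scan temperature coefficients for i/i+2 periodicity
#'
#' Flags residues whose amide temperature coefficient is less negative than
#' both sequence neighbors' by at least `margin`: an alternating pattern of
#' relatively protected amides that may reflect transient intermolecular
#' beta-strand contacts. Residues lacking a coefficient on either side
#' cannot be flagged.
#'
#' @param residue_index Residue indices (sorted or not).
#' @param slope_ppb_K Temperature coefficients, same length (`NA` allowed).
#' @param margin Required contrast against each neighbor, ppb/K (default 1).
#' @return Integer vector of flagged residue indices.
#' @examples
#' periodicity_scan(1:5, c(-7.4, -5.9, -8.9, -4.5, -9.0))  # flags 2 and 4
#' @export
periodicity_scan <- function(residue_index, slope_ppb_K, margin = 1.0) {
  if (length(residue_index) != length(slope_ppb_K))
    stop("inputs must have equal length")
  ord <- order(residue_index)
  ri <- residue_index[ord]; s <- slope_ppb_K[ord]
  if (sum(is.finite(s)) < 3L)
    stop("need coefficients for at least 3 residues")
  flagged <- integer()
  for (k in seq_along(ri)) {
    prev <- which(ri == ri[k] - 1L); nxt <- which(ri == ri[k] + 1L)
    if (!length(prev) || !length(nxt)) next
    if (any(!is.finite(c(s[k], s[prev], s[nxt])))) next
    if (s[k] >= s[prev] + margin && s[k] >= s[nxt] + margin)
      flagged <- c(flagged, ri[k])
  }
  flagged
}
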