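# Characterization dataset for the eight Ala-Val-X-Val-Leu pentapeptide
# systems (X = Ser, Thr, (2S,3R)-CF3-Thr, (2S,3S)-CF3-Thr; Boc-protected "a"
# and free-amine "b" forms), transcribed cell for cell from the systems'
# published NMR/MD characterization: HA and CA chemical shift deviations,
# 3J couplings, amide temperature coefficients and MD-derived beta-basin
# probabilities. These tables are the package's reference inputs: the
# descriptor rules are exercised against them and the synthetic-ensemble
# defaults are calibrated to the beta probabilities.

study_sequences <- function() {
  list("1" = c("ALA", "VAL", "SER", "VAL", "LEU"),
       "2" = c("ALA", "VAL", "THR", "VAL", "LEU"),
       "3" = c("ALA", "VAL", "TFR", "VAL", "LEU"),
       "4" = c("ALA", "VAL", "TFS", "VAL", "LEU"))
}

long_table <- function(values_by_peptide, value_col, notes_by_peptide = NULL) {
  seqs <- study_sequences()
  rows <- list()
  for (pep in names(values_by_peptide)) {
    num <- substr(pep, 1, 1)
    v <- values_by_peptide[[pep]]
    d <- data.frame(peptide = pep,
                    protection = if (endsWith(pep, "a")) "boc" else "free",
                    residue_index = seq_along(v),
                    residue_code = seqs[[num]][seq_along(v)])
    d[[value_col]] <- v
    d$note <- if (is.null(notes_by_peptide)) "" else notes_by_peptide[[pep]]
    rows[[pep]] <- d
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' HA chemical shift deviations of the eight pentapeptides
#'
#' Per-residue 1HA chemical shift deviations (CSD, ppm; observed minus
#' random coil, 298 K in CD3OH) for the eight pentapeptide systems. Entries
#' for the CF3-threonine residues are `NA` (no random-coil reference
#' exists). Terminal-residue entries are retained as printed; CSD analyses
#' of backbone propensity use the central residues.
#'
#' @return Data frame with columns `peptide`, `protection`, `residue_index`,
#'   `residue_code`, `csd_ppm`, `note`.
#' @export
csd_halpha_table <- function() {
  long_table(list(
    "1a" = c(-0.23, 0.09, 0.01, 0.15, 0.09),
    "2a" = c(-0.20, 0.13, 0.04, 0.13, 0.11),
    "3a" = c(-0.22, 0.09, NA,   0.17, 0.07),
    "4a" = c(-0.19, 0.13, NA,   0.15, 0.09),
    "1b" = c(-0.35, 0.14, 0.04, 0.15, 0.08),
    "2b" = c(-0.41, 0.14, 0.05, 0.12, 0.07),
    "3b" = c(-0.33, 0.14, NA,   0.18, 0.07),
    "4b" = c(-0.35, 0.22, NA,   0.17, 0.08)), "csd_ppm")
}

#' CA chemical shift deviations of the eight pentapeptides
#'
#' Per-residue 13CA chemical shift deviations (ppm, 298 K in CD3OH);
#' see [csd_halpha_table()] for conventions.
#'
#' @return Data frame in the same layout as [csd_halpha_table()].
#' @export
csd_calpha_table <- function() {
  long_table(list(
    "1a" = c(-0.6, -2.0, -1.6, -2.1, -2.8),
    "2a" = c(-0.9, -2.0, -1.8, -2.2, -2.9),
    "3a" = c(-0.8, -2.5, NA,   -2.4, -2.7),
    "4a" = c(-0.8, -1.6, NA,   -1.9, -2.9),
    "1b" = c(-2.1, -1.7, -1.8, -2.2, -2.8),
    "2b" = c(-2.1, -1.6, -1.9, -2.3, -2.9),
    "3b" = c(-2.2, -2.0, NA,   -2.4, -2.7),
    "4b" = c(-2.1, -2.0, NA,   -2.4, -2.8)), "csd_ppm")
}

#' 3J(HN-HA) couplings of the eight pentapeptides
#'
#' Experimental three-bond HN-HA coupling constants (Hz, CD3OH; mostly
#' 271 K, `note` = `"298K"` where measured at 298 K). `NA` with empty note
#' means not measured (the free-amine Ala1 amide); `NA` with note
#' `"broad"` means the peak was too broad to resolve.
#'
#' @return Data frame with columns `peptide`, `protection`, `residue_index`,
#'   `residue_code`, `j_hz`, `note`.
#' @export
jhnha_table <- function() {
  long_table(list(
    "1a" = c(6.8, 8.2, 7.5, 8.9, 7.8),
    "2a" = c(6.9, 8.3, 8.4, 8.8, 7.8),
    "3a" = c(7.1, 8.9, 9.1, 9.2, 7.6),
    "4a" = c(6.8, 7.7, 8.6, 9.0, 7.7),
    "1b" = c(NA,  8.3, 7.6, 8.6, 7.6),
    "2b" = c(NA,  NA,  8.4, 8.7, 7.7),
    "3b" = c(NA,  8.7, 9.0, 8.2, 7.4),
    "4b" = c(NA,  8.9, 9.0, 8.9, 7.6)), "j_hz",
    notes_by_peptide = list(
      "1a" = rep("", 5),
      "2a" = rep("298K", 5),
      "3a" = rep("", 5),
      "4a" = rep("", 5),
      "1b" = c("", "", "298K", "298K", "298K"),
      "2b" = c("", "broad", "", "", ""),
      "3b" = rep("", 5),
      "4b" = rep("", 5)))
}

#' 3J(HA-HB) couplings of the eight pentapeptides
#'
#' Experimental HA-HB coupling constants (Hz) informing the chi1 rotamer
#' state. Residues with two resolved HB protons (Leu; Ser in some forms)
#' carry both couplings (`j_hz`, `j_hz2`); beta-branched residues carry one.
#'
#' @return Data frame with columns `peptide`, `protection`, `residue_index`,
#'   `residue_code`, `j_hz`, `j_hz2`, `note`.
#' @export
jhahb_table <- function() {
  t1 <- long_table(list(
    "1a" = c(7.1, 6.7, 6.0, 6.6, 5.1),
    "2a" = c(7.2, 7.3, 4.9, 6.9, 5.0),
    "3a" = c(7.3, 7.1, 6.4, 6.5, 6.0),
    "4a" = c(7.0, 7.0, 2.5, 7.1, 5.0),
    "1b" = c(7.2, 6.6, 7.5, 6.6, 5.3),
    "2b" = c(7.2, 7.1, 4.6, 7.1, 5.6),
    "3b" = c(7.3, 7.3, 6.7, 7.0, 5.3),
    "4b" = c(7.2, 8.2, 2.0, 7.5, 5.4)), "j_hz")
  second <- list(
    "1a" = c(NA, NA, 6.0, NA, 10.6),
    "2a" = c(NA, NA, NA, NA, 10.6),
    "3a" = c(NA, NA, NA, NA, 10.0),
    "4a" = c(NA, NA, NA, NA, 10.5),
    "1b" = c(NA, NA, 7.5, NA, 10.3),
    "2b" = c(NA, NA, NA, NA, 10.0),
    "3b" = c(NA, NA, NA, NA, 10.3),
    "4b" = c(NA, NA, NA, NA, 10.5))
  t1$j_hz2 <- unlist(second[unique(t1$peptide)], use.names = FALSE)
  t1[, c("peptide", "protection", "residue_index", "residue_code",
         "j_hz", "j_hz2", "note")]
}

#' Amide temperature coefficients of the eight pentapeptides
#'
#' Experimental amide-proton temperature coefficients (ppb/K, CD3OH).
#' `NA`: not measurable (free-amine Ala1 has no amide proton signal).
#'
#' @return Data frame with columns `peptide`, `protection`, `residue_index`,
#'   `residue_code`, `slope_ppb_K`, `note`.
#' @export
tempco_table <- function() {
  long_table(list(
    "1a" = c(-7.8, -6.4, -7.7, -8.0, -7.4),
    "2a" = c(-7.4, -5.8, -7.5, -7.6, -7.9),
    "3a" = c(-6.5, -5.3, -7.4, -7.4, -5.0),
    "4a" = c(-7.4, -5.9, -8.9, -4.5, -9.0),
    "1b" = c(NA, -6.1, -7.8, -7.8, -7.0),
    "2b" = c(NA, -5.5, -8.1, -8.0, -7.7),
    "3b" = c(NA, -6.6, -8.5, -9.0, -6.0),
    "4b" = c(NA, -5.5, -8.3, -4.6, -7.9)), "slope_ppb_K")
}

#' MD-derived beta-conformation probabilities of the central residues
#'
#' Percent probability of each central residue (positions 2-4) to occupy
#' the beta basin of psi, and the printed global extension probability `P`
#' (all three central residues simultaneously in beta, the product of the
#' three). These per-residue values double as the default generator weights
#' of the synthetic-ensemble pipeline.
#'
#' @return Data frame with columns `peptide`, `protection`, `p_val2`,
#'   `p_x3`, `p_val4`, `p_global` (all percent).
#' @export
beta_probability_table <- function() {
  d <- data.frame(
    peptide = c("1a", "2a", "3a", "4a", "1b", "2b", "3b", "4b"),
    protection = rep(c("boc", "free"), each = 4),
    p_val2   = c(59.9, 53.5, 59.7, 67.1, 76.5, 64.8, 63.3, 77.9),
    p_x3     = c(51.4, 91.1, 31.7, 82.7, 50.3, 73.5, 59.4, 85.6),
    p_val4   = c(55.8, 61.0, 69.9, 75.6, 64.9, 59.1, 74.7, 74.8),
    p_global = c(17.2, 29.7, 13.2, 42.0, 25.0, 28.2, 28.1, 49.9))
  d
}

#' Write the characterization tables as CSV fixtures
#'
#' Emits the six reference tables to `outdir` as plain CSV files
#' (`csd_halpha.csv`, `csd_calpha.csv`, `jhnha.csv`, `jhahb.csv`,
#' `tempco.csv`, `beta_probability.csv`). Emission is deterministic:
#' re-running produces byte-identical files.
#'
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(csd_halpha = csd_halpha_table(),
               csd_calpha = csd_calpha_table(),
               jhnha = jhnha_table(),
               jhahb = jhahb_table(),
               tempco = tempco_table(),
               beta_probability = beta_probability_table())
  paths <- character()
  for (nm in names(tabs)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE, quote = FALSE, na = "")
    paths[nm] <- p
  }
  invisible(paths)
}
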