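#' Residue alphabet
#'
#' Three-letter residue codes accepted by [peptide_spec()]. Besides the 20
#' standard amino acids this includes two nonstandard codes for the
#' 4,4,4-trifluorothreonine diastereomers: \code{"TFR"} for
#' (2S,3R)-CF3-threonine and \code{"TFS"} for (2S,3S)-CF3-threonine
#' (the 3S diastereomer has the same relative side-chain configuration as
#' natural threonine).
#'
#' @return Character vector of valid residue codes.
#' @export
residue_alphabet <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
    "TFR", "TFS")
}

#' Peptide specification
#'
#' Describes a linear peptide: its residue sequence and terminal chemistry.
#' The systems this package was written around are pentapeptides
#' Ala-Val-X-Val-Leu with X one of Ser, Thr, (2S,3R)-CF3-Thr or
#' (2S,3S)-CF3-Thr, carrying either a Boc carbamate or a free amine at the
#' N-terminus and a methyl ester at the C-terminus; arbitrary sequences of
#' length >= 2 are accepted.
#'
#' @param sequence Character vector of residue codes from
#'   [residue_alphabet()] (case-insensitive), length >= 2.
#' @param n_terminus `"boc"` (carbamate cap; its carbonyl carbon provides the
#'   reference atom for phi of residue 1) or `"free-amine"`.
#' @param c_terminus `"methyl-ester"` (the only supported C-terminal
#'   chemistry; the ester carbonyl carbon is the chain's last backbone
#'   carbon).
#' @param label Optional short label for reports (e.g. `"4a"`).
#' @return An object of class `"peptide_spec"`.
#' @examples
#' peptide_spec(c("ALA", "VAL", "TFS", "VAL", "LEU"), n_terminus = "boc",
#'              label = "4a")
#' @export
peptide_spec <- function(sequence,
                         n_terminus = c("boc", "free-amine"),
                         c_terminus = "methyl-ester",
                         label = NULL) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) < 2L)
    stop("peptide sequence must contain at least 2 residues")
  bad <- setdiff(sequence, residue_alphabet())
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  n_terminus <- match.arg(n_terminus)
  c_terminus <- match.arg(c_terminus)
  structure(
    list(sequence = sequence, n_terminus = n_terminus,
         c_terminus = c_terminus,
         label = if (is.null(label)) paste(sequence, collapse = "-") else label),
    class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat("Peptide", x$label, ":",
      if (x$n_terminus == "boc") "Boc-" else "H2N-",
      paste(x$sequence, collapse = "-"), "-OMe\n", sep = "")
  invisible(x)
}

#' @export
length.peptide_spec <- function(x) length(x$sequence)

#' The eight pentapeptide systems of the study
#'
#' Returns the peptide specifications for the eight studied pentapeptides:
#' Ala-Val-X-Val-Leu-OMe with X = Ser (1), Thr (2), (2S,3R)-CF3-Thr (3),
#' (2S,3S)-CF3-Thr (4), each as the Boc-protected ("a") and free-amine ("b")
#' form.
#'
#' @return Named list of eight [peptide_spec()] objects
#'   (`"1a"` ... `"4b"`).
#' @export
study_peptides <- function() {
  centers <- c("1" = "SER", "2" = "THR", "3" = "TFR", "4" = "TFS")
  out <- list()
  for (num in names(centers)) {
    seq5 <- c("ALA", "VAL", centers[[num]], "VAL", "LEU")
    out[[paste0(num, "a")]] <-
      peptide_spec(seq5, n_terminus = "boc", label = paste0(num, "a"))
    out[[paste0(num, "b")]] <-
      peptide_spec(seq5, n_terminus = "free-amine", label = paste0(num, "b"))
  }
  out
}

#' Wrap angles into (-180, 180]
#'
#' Maps angles in degrees onto the wrapped interval (-180, 180]; -180 maps
#' to +180.
#'
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @examples
#' wrap_angle(c(190, -180, 540))
#' @export
wrap_angle <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}
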