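#' Write / read a multi-model PDB ensemble
#'
#' `write_ensemble()` writes every frame of an `ensemble_3d` as one MODEL /
#' ENDMDL block of ATOM records (chain A, 1-based residue numbering, the
#' N-terminal cap carbonyl as residue 0 when present). `read_ensemble()`
#' parses such a file back; coordinates survive the round trip to the
#' format's 3-decimal (0.001 Angstrom) precision. Every model must contain
#' the same atoms in the same order; violations and malformed records are
#' reported with the offending line number.
#'
#' @param ensemble An `ensemble_3d` with at least one model.
#' @param path File path.
#' @return `write_ensemble()` returns `path` invisibly; `read_ensemble()`
#'   returns an `ensemble_3d` (its `spec` reconstructed from the residue
#'   names found in the file).
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble_3d"))
  nf <- nrow(ensemble$xyz)
  if (nf < 1L) stop("refusing to write an empty ensemble (0 models)")
  at <- ensemble$atoms
  na <- nrow(at)
  elem <- substr(at$name, 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(nf)) {
    writeLines(sprintf("MODEL %8d", m), con)
    x <- ensemble$xyz[m, ]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(na), format_atom_name(at$name), at$resid, "A", at$resno,
      x[3 * seq_len(na) - 2], x[3 * seq_len(na) - 1], x[3 * seq_len(na)],
      1.00, 0.00, elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# PDB column 13-16 atom-name convention: names of <4 chars start in col 14
format_atom_name <- function(name) {
  ifelse(nchar(name) >= 4, substr(name, 1, 4), paste0(" ", name))
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- NULL      # list of per-atom rows for the model being read
  cur_meta <- NULL
  in_model <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- substr(line, 1, 6)
    if (startsWith(rec, "MODEL")) {
      if (in_model)
        stop("PDB parse error at line ", ln, ": MODEL inside an open MODEL")
      in_model <- TRUE
      cur <- list(); cur_meta <- list()
    } else if (startsWith(rec, "ENDMDL")) {
      if (!in_model)
        stop("PDB parse error at line ", ln, ": ENDMDL without MODEL")
      in_model <- FALSE
      models[[length(models) + 1L]] <-
        list(xyz = do.call(rbind, cur), meta = do.call(rbind, cur_meta))
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (!in_model) { # single-model files without MODEL records
        in_model <- TRUE
        cur <- list(); cur_meta <- list()
      }
      xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                           substr(line, 39, 46),
                                           substr(line, 47, 54))))
      if (any(is.na(xyz)))
        stop("PDB parse error at line ", ln, ": unreadable coordinates")
      resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
      if (is.na(resno))
        stop("PDB parse error at line ", ln, ": unreadable residue number")
      cur[[length(cur) + 1L]] <- xyz
      cur_meta[[length(cur_meta) + 1L]] <- data.frame(
        name = trimws(substr(line, 13, 16)),
        resno = resno,
        resid = trimws(substr(line, 18, 20)))
    }
  }
  if (in_model)
    models[[length(models) + 1L]] <-
      list(xyz = do.call(rbind, cur), meta = do.call(rbind, cur_meta))
  if (!length(models)) stop("PDB parse error: no ATOM records found")

  meta <- models[[1]]$meta
  na <- nrow(meta)
  for (m in seq_along(models)) {
    if (nrow(models[[m]]$meta) != na)
      stop("model ", m, " has ", nrow(models[[m]]$meta),
           " atoms; model 1 has ", na, " (all models must match)")
    if (!identical(models[[m]]$meta$name, meta$name) ||
        !identical(models[[m]]$meta$resno, meta$resno))
      stop("model ", m, " atom ordering differs from model 1")
  }
  xyz <- t(vapply(models, function(m) as.vector(t(m$xyz)),
                  numeric(3L * na)))

  res <- unique(meta[meta$resno >= 1L & meta$name == "CA",
                     c("resno", "resid")])
  codes <- res$resid[order(res$resno)]
  known <- all(codes %in% residue_alphabet())
  spec <- if (known && length(codes) >= 2) {
    peptide_spec(codes,
                 n_terminus = if (any(meta$resno == 0L)) "boc" else "free-amine")
  } else {
    structure(list(sequence = codes, n_terminus = "free-amine",
                   c_terminus = "methyl-ester",
                   label = paste(codes, collapse = "-")),
              class = "peptide_spec")
  }
  structure(list(xyz = xyz, atoms = meta, spec = spec,
                 geometry = NULL),
            class = "ensemble_3d")
}
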