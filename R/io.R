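# Readers and writers for the plain-text formats the pipeline consumes.

#' Read a titration series from CSV
#'
#' Expected columns: `inhibitor_nM` (or `inhibitor_uM`, converted to nM),
#' `replicate`, `activity_fraction`.
#'
#' @param path CSV file path.
#' @param enzyme_total optional total enzyme concentration (nM).
#' @return a [titration_series()].
#' @export
read_titration_csv <- function(path, enzyme_total = NULL) {
  d <- utils::read.csv(path)
  unit <- if ("inhibitor_uM" %in% names(d)) "uM"
          else if ("inhibitor_nM" %in% names(d)) "nM"
          else stop("expected an `inhibitor_nM` or `inhibitor_uM` column",
                    call. = FALSE)
  conc <- d[[paste0("inhibitor_", unit)]]
  rep_col <- if ("replicate" %in% names(d)) d$replicate else NULL
  titration_series(conc, d$activity_fraction, rep_col,
                   enzyme_total = enzyme_total, unit = unit)
}

#' Write a titration series to CSV
#'
#' @param series a [titration_series()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  d <- as.data.frame(series)
  utils::write.csv(
    data.frame(inhibitor_nM = d$inhibitor_total,
               replicate = d$replicate,
               activity_fraction = d$activity_fraction),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an ion-envelope peak list from CSV
#'
#' Expected columns: `mz` and optionally `intensity`.
#'
#' @param path CSV file path.
#' @return an [ion_envelope()].
#' @export
read_envelope_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"mz" %in% names(d)) stop("expected an `mz` column", call. = FALSE)
  ion_envelope(d$mz, if ("intensity" %in% names(d)) d$intensity else NULL)
}

#' Write an ion envelope to CSV
#' @param env an [ion_envelope()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_envelope_csv <- function(env, path) {
  utils::write.csv(as.data.frame(env), path, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return list of [protein_sequence()]s (named by record id).
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    protein_sequence(names(set)[i], as.character(set[[i]]))
  })
  names(out) <- vapply(out, function(s) s$id, character(1L))
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs a [protein_sequence()] or list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, function(s) s$residues,
                                        character(1L)))
  names(set) <- vapply(seqs, function(s) s$id, character(1L))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an aligned FASTA multiple alignment
#'
#' @param path aligned-FASTA file path (equal-width records, `-` gaps).
#' @return named character vector of aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readAAMultipleAlignment(path, format = "fasta")
  out <- as.character(set)
  stats::setNames(out, rownames(set))
}

#' Read a peptide list (one peptide per line)
#'
#' @param path text file path; blank lines and `#` comments are skipped.
#' @return character vector of peptides.
#' @export
read_peptide_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
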