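#' Read genome sequences from a FASTA file
#'
#' Reads one record per FASTA header into a genome table. Sequences are
#' normalized to uppercase, `U` is mapped to `T`, and any character outside
#' `A`, `C`, `G`, `T`, `N`, `U` raises an error. Ambiguous positions (`N`)
#' are retained in the sequence but excluded from composition statistics
#' downstream.
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return A tibble with one row per record and columns `id`, `sequence`,
#'   `length` (bp) and `n_ambiguous` (count of non-ACGT characters).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "acgtACGT", ">g2", "TTTT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_phagemech(paste0("FASTA file not found: ", path), "phagemech_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop_phagemech("FASTA file contains no records", "phagemech_empty_fasta")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_phagemech(
      paste0("duplicate FASTA identifiers: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "phagemech_duplicate_ids"
    )
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    chars <- unique(unlist(stringr::str_extract_all(seqs[bad], "[^ACGTN]")))
    stop_phagemech(
      paste0("illegal characters in record(s) ",
             paste(ids[bad], collapse = ", "), ": ",
             paste(chars, collapse = " ")),
      "phagemech_illegal_characters"
    )
  }
  genome_tbl(id = ids, sequence = seqs)
}

#' Construct a genome table from sequences in memory
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of uppercase DNA sequences over
#'   `{A,C,G,T,N}` (same length as `id`).
#' @return A tibble with columns `id`, `sequence`, `length`, `n_ambiguous`.
#' @export
genome_tbl <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  tibble(
    id = as.character(id),
    sequence = as.character(sequence),
    length = nchar(sequence),
    n_ambiguous = nchar(sequence) - stringr::str_count(sequence, "[ACGT]")
  )
}

#' Write a genome table to FASTA
#'
#' @param genomes A genome tibble (see [read_fasta()]).
#' @param path Output path.
#' @param comment Optional character scalar appended to each header line
#'   (e.g. an echo of the simulation spec).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, comment = NULL) {
  set <- Biostrings::BStringSet(genomes$sequence)
  names(set) <- if (is.null(comment)) genomes$id else paste(genomes$id, comment)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' GC content of each genome, in percent
#'
#' Computes `100 * (#G + #C) / (#A + #C + #G + #T)` per genome; ambiguous
#' characters are excluded from both numerator and denominator.
#'
#' @param genomes A genome tibble.
#' @return The input tibble (without `sequence`) with a `gc_percent` column.
#' @export
#' @examples
#' g <- genome_tbl(c("x", "y"), c("GCGC", "ATAT"))
#' gc_content(g)
gc_content <- function(genomes) {
  n_gc <- stringr::str_count(genomes$sequence, "[GC]")
  n_acgt <- stringr::str_count(genomes$sequence, "[ACGT]")
  if (any(n_acgt == 0L)) {
    stop_phagemech("sequence has no unambiguous characters",
                   "phagemech_all_ambiguous")
  }
  genomes |>
    select(-"sequence") |>
    mutate(gc_percent = 100 * n_gc / n_acgt)
}

#' Write a positional track as TSV
#'
#' Writes a two-column TSV (`position`, `value`) with 1-based genome
#' coordinates; undefined values are written as the literal string `NA`.
#'
#' @param track A data frame with columns `position` (1-based integer) and
#'   `value` (numeric, `NA` where undefined), or a bare numeric vector
#'   (positions then default to `1..length`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(track, path) {
  if (is.numeric(track)) {
    track <- tibble(position = seq_along(track), value = as.numeric(track))
  }
  stopifnot(all(c("position", "value") %in% names(track)))
  readr::write_tsv(track[, c("position", "value")], path, na = "NA")
  invisible(path)
}

#' Read a positional track written by [write_tracks()]
#'
#' @param path Path to a TSV with columns `position` and `value`.
#' @return A tibble with columns `position` and `value`.
#' @export
read_tracks <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(),
    value = readr::col_double()
  ), na = "NA", progress = FALSE)
}
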