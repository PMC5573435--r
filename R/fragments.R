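# Fragment tables: the package-wide representation of sequence collections.
# A fragment table is a tibble with columns `id` (unique), `sequence`
# (A/C/G/T/N after ingest) and optionally `label` (species of origin).

#' Build a validated fragment table
#'
#' Normalises a data frame of sequences into the tibble format used
#' throughout the package: one row per fragment with a unique `id`, an
#' uppercased `sequence` over the alphabet A, C, G, T, N, and an optional
#' `label` column carrying the (true or assigned) species name.
#' Lowercase (soft-masked) bases are uppercased; any character outside
#' the alphabet is rejected with its position.
#'
#' @param x A data frame with columns `id` and `sequence`, and optionally
#'   `label`. Alternatively a named character vector of sequences (names
#'   become ids).
#' @param labels Optional named character vector or two-column data frame
#'   (`id`, `label`) mapping fragment ids to species names.
#' @return A tibble with columns `id`, `sequence` and, when labels are
#'   available, `label`.
#' @examples
#' as_fragments(c(f1 = "acgtN", f2 = "TTTT"))
#' @export
as_fragments <- function(x, labels = NULL) {
  if (is.character(x)) {
    if (is.null(names(x))) {
      abort("A character vector of sequences must be named; names become ids.")
    }
    x <- tibble(id = names(x), sequence = unname(x))
  }
  x <- as_tibble(x)
  if (!all(c("id", "sequence") %in% names(x))) {
    abort("A fragment table needs `id` and `sequence` columns.")
  }
  x$id <- as.character(x$id)
  x$sequence <- toupper(x$sequence)
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    abort(paste0("Duplicated fragment ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (any(!nzchar(x$sequence))) {
    abort("Every fragment must have a sequence of length >= 1.")
  }
  bad <- stringr::str_locate(x$sequence, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf(
      "Fragment '%s' contains non-ACGTN character '%s' at position %d.",
      x$id[i], substr(x$sequence[i], bad[i], bad[i]), bad[i]
    ))
  }
  if (!is.null(labels)) {
    lab <- if (is.data.frame(labels)) {
      setNames(as.character(labels[[2]]), as.character(labels[[1]]))
    } else {
      labels
    }
    x$label <- unname(lab[x$id])
  }
  keep <- intersect(c("id", "sequence", "label"), names(x))
  x[, keep]
}

#' Read fragments from a FASTA file
#'
#' Reads a (multi-record, possibly line-wrapped) FASTA file into a
#' fragment table. The first whitespace-delimited token of each header is
#' used as the fragment id. An optional two-column tab-separated mapping
#' file (`sequence_id<TAB>species_name`, no header) attaches species
#' labels.
#'
#' @param fasta Path to a FASTA file.
#' @param labels Optional path to a two-column TSV label mapping, or a
#'   data frame / named vector as in [as_fragments()].
#' @return A fragment tibble (see [as_fragments()]).
#' @export
read_fragments_fasta <- function(fasta, labels = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    labels <- read_label_map(labels)
  }
  as_fragments(tibble(id = ids, sequence = as.character(seqs)), labels = labels)
}

#' Read a two-column id-to-species label mapping
#'
#' @param path TSV with two columns, `sequence_id<TAB>species_name`,
#'   no header line.
#' @return A tibble with columns `id` and `label`.
#' @export
read_label_map <- function(path) {
  m <- readr::read_tsv(path, col_names = c("id", "label"),
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  as_tibble(m)
}

#' Write fragments to FASTA (and optionally a label mapping TSV)
#'
#' @param fragments A fragment tibble.
#' @param fasta Output FASTA path.
#' @param labels Optional output path for the `id<TAB>label` TSV; requires
#'   a `label` column.
#' @return `fasta`, invisibly.
#' @export
write_fragments_fasta <- function(fragments, fasta, labels = NULL) {
  x <- Biostrings::DNAStringSet(setNames(fragments$sequence, fragments$id))
  Biostrings::writeXStringSet(x, fasta)
  if (!is.null(labels)) {
    if (!"label" %in% names(fragments)) abort("No `label` column to write.")
    readr::write_tsv(fragments[, c("id", "label")], labels, col_names = FALSE)
  }
  invisible(fasta)
}

#' Reverse-complement nucleotide sequences
#'
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
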