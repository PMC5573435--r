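# Best-hit local-alignment fallback for diffident fragments.
#
# Seeding: exact-word index (default word size 11) over the forward
# strand of the reference; queries are searched in both orientations.
# Extension: Smith-Waterman local alignment (Biostrings) of the query
# against a window of the candidate subject around the seeded diagonal,
# with the classic nucleotide scoring match +2, mismatch -3, gap open 5,
# gap extend 2. Raw scores are converted to bit scores with the
# Karlin-Altschul parameters for that scoring (gapped lambda = 0.625,
# K = 0.41) and e-value = m * n * 2^(-bitscore), m = query length,
# n = total reference length.

.KA_LAMBDA <- 0.625
.KA_K <- 0.41

#' Alignment fallback policy
#'
#' Controls when a best hit is accepted. The default policy mirrors a
#' plain nucleotide search (e-value cutoff 10, no identity floor); the
#' strict policy additionally requires e-value <= 1e-5 and percent
#' identity >= 97.5, the setting used for noisy real-world data where a
#' wrong label is worse than an `unknown` tag.
#'
#' @param preset `"default"` or `"strict"`, or leave unnamed arguments to
#'   set fields directly.
#' @param e_value_cutoff Maximum accepted e-value (> 0).
#' @param min_identity Optional minimum percent identity in `[0, 100]`.
#' @param word_size Exact-match seed length for the internal aligner.
#' @param max_candidates Number of top seeded (subject, strand) candidates
#'   to extend per query.
#' @return A `fallback_policy` list.
#' @examples
#' fallback_policy()
#' fallback_policy("strict")
#' @export
fallback_policy <- function(preset = c("default", "strict"),
                            e_value_cutoff = NULL, min_identity = NULL,
                            word_size = 11, max_candidates = 8) {
  preset <- match.arg(preset)
  p <- list(
    e_value_cutoff = if (preset == "strict") 1e-5 else 10,
    min_identity = if (preset == "strict") 97.5 else NA_real_,
    word_size = as.integer(word_size),
    max_candidates = as.integer(max_candidates)
  )
  if (!is.null(e_value_cutoff)) p$e_value_cutoff <- e_value_cutoff
  if (!is.null(min_identity)) p$min_identity <- min_identity
  if (p$e_value_cutoff <= 0) abort("`e_value_cutoff` must be positive.")
  if (!is.na(p$min_identity) && (p$min_identity < 0 || p$min_identity > 100)) {
    abort("`min_identity` must be in [0, 100].")
  }
  structure(p, class = "fallback_policy")
}

#' Build a searchable seed index over reference sequences
#'
#' Indexes every exact word of length `word_size` on the given strand of
#' each reference sequence (queries are later searched in both
#' orientations, so both strands of the reference are effectively
#' reachable). Every subject must carry a species label.
#'
#' @param reference A fragment tibble of reference sequences with a
#'   `label` column.
#' @param word_size Seed word length (default 11).
#' @return A `reference_index` object.
#' @export
build_reference_index <- function(reference, word_size = 11) {
  reference <- as_fragments(reference)
  if (!nrow(reference)) abort("The reference set is empty.")
  if (!"label" %in% names(reference) || anyNA(reference$label)) {
    bad <- if (!"label" %in% names(reference)) reference$id else
      reference$id[is.na(reference$label)]
    abort(paste0("Reference sequence(s) without a species label: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  word_size <- check_k(word_size)
  codes <- lapply(reference$sequence,
                  function(s) rolling_codes(seq_to_digits(s), word_size))
  subject <- rep.int(seq_along(codes), lengths(codes))
  pos <- unlist(lapply(lengths(codes), seq_len), use.names = FALSE)
  code <- unlist(codes, use.names = FALSE)
  keep <- !is.na(code)
  ord <- order(code[keep], subject[keep], pos[keep], method = "radix")
  structure(
    list(
      word_size = word_size,
      code = code[keep][ord], subject = subject[keep][ord],
      pos = pos[keep][ord],
      ids = reference$id, labels = reference$label,
      sequences = reference$sequence,
      total_length = sum(nchar(reference$sequence))
    ),
    class = "reference_index"
  )
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf(
    "Reference seed index: %d sequences (%d bp, %d species), word size %d\n",
    length(x$ids), x$total_length, length(unique(x$labels)), x$word_size))
  invisible(x)
}

#' Look up the postings of seed words
#'
#' @param index A `reference_index`.
#' @param codes Integer word codes (as from [encode_kmer()] at the
#'   index's word size).
#' @return A tibble `query_pos` (index into `codes`), `subject`
#'   (subject row number), `pos` (1-based word start in the subject).
#' @export
index_lookup <- function(index, codes) {
  lo <- findInterval(codes - 0.5, index$code) + 1L
  hi <- findInterval(codes, index$code)
  n <- pmax(hi - lo + 1L, 0L)
  take <- unlist(purrr::map2(lo, hi, function(a, b) if (b >= a) a:b else integer(0)),
                 use.names = FALSE)
  tibble(
    query_pos = rep.int(seq_along(codes), n),
    subject = index$subject[take],
    pos = index$pos[take]
  )
}

ka_bitscore <- function(raw_score) {
  (.KA_LAMBDA * raw_score - log(.KA_K)) / log(2)
}

#' E-value of an alignment score
#'
#' Karlin-Altschul statistics for the internal scoring scheme:
#' `bitscore = (lambda * S - ln K) / ln 2` and
#' `e = m * n * 2^(-bitscore)`.
#'
#' @param raw_score Raw Smith-Waterman score.
#' @param query_length Query length m (bp).
#' @param db_length Total reference length n (bp).
#' @return A list with `bit_score` and `e_value`.
#' @export
alignment_evalue <- function(raw_score, query_length, db_length) {
  bit <- ka_bitscore(raw_score)
  list(bit_score = bit,
       e_value = as.numeric(query_length) * as.numeric(db_length) * 2^(-bit))
}

.sub_matrix <- NULL
sub_matrix <- function() {
  if (is.null(.sub_matrix)) {
    utils::assignInMyNamespace(
      ".sub_matrix",
      Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                               baseOnly = TRUE))
  }
  .sub_matrix
}

# Smith-Waterman extension of one query against a subject window.
# Returns NULL when the local alignment scores <= 0.
extend_candidate <- function(query, subject_seq, window) {
  sub <- substr(subject_seq, window[1], window[2])
  al <- Biostrings::pairwiseAlignment(
    query, sub, type = "local",
    substitutionMatrix = sub_matrix(),
    gapOpening = 5, gapExtension = 2
  )
  s <- Biostrings::score(al)
  if (s <= 0) return(NULL)
  p <- Biostrings::alignedPattern(al)
  len <- Biostrings::nchar(al)
  nmat <- Biostrings::nmatch(al)
  list(
    score = s,
    identity = 100 * nmat / len,
    length = len,
    mismatch = Biostrings::nmismatch(al),
    gapopen = length(Biostrings::indel(al)@insertion[[1]]) +
      length(Biostrings::indel(al)@deletion[[1]]),
    qstart = al@pattern@range@start,
    qend = al@pattern@range@start + al@pattern@range@width - 1L,
    sstart = window[1] + al@subject@range@start - 1L,
    send = window[1] + al@subject@range@start + al@subject@range@width - 2L
  )
}

#' Best local-alignment hit of one query against the reference
#'
#' Seeds the query (both orientations) against the index, extends the
#' top seeded candidates by local alignment, converts raw scores to bit
#' scores and e-values, and returns the hit with the lowest e-value
#' (ties: higher bit score, then lexicographically lowest subject id).
#' Returns `NULL` when no candidate satisfies the policy (e-value cutoff
#' and, when set, identity floor) - absence is a value, not an error.
#'
#' @param query A single sequence (character) or one-row fragment tibble.
#' @param index A `reference_index` from [build_reference_index()].
#' @param policy A [fallback_policy()].
#' @return A one-row tibble with `subject_id`, `subject_species`,
#'   `percent_identity`, `alignment_length`, `bit_score`, `e_value`,
#'   `strand`, or `NULL`.
#' @export
best_hit <- function(query, index, policy = fallback_policy()) {
  if (is.data.frame(query)) query <- query$sequence[1]
  query <- toupper(query)
  hits <- align_candidates(query, index, policy)
  if (is.null(hits) || !nrow(hits)) return(NULL)
  hits <- hits[hits$e_value <= policy$e_value_cutoff, , drop = FALSE]
  if (!is.na(policy$min_identity)) {
    hits <- hits[hits$percent_identity >= policy$min_identity, , drop = FALSE]
  }
  if (!nrow(hits)) return(NULL)
  ord <- order(hits$e_value, -hits$bit_score, hits$subject_id, method = "radix")
  hits[ord[1], , drop = FALSE]
}

# all extended candidate hits for a query (one row per subject x strand)
align_candidates <- function(query, index, policy) {
  ws <- index$word_size
  m <- nchar(query)
  if (m < ws) return(NULL)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    codes <- rolling_codes(seq_to_digits(q), ws)
    qpos <- which(!is.na(codes))
    if (!length(qpos)) next
    seeds <- index_lookup(index, codes[qpos])
    if (!nrow(seeds)) next
    seeds$qstart <- qpos[seeds$query_pos]
    # rank candidate subjects by seed support, extend the top few
    support <- sort(table(seeds$subject), decreasing = TRUE)
    cand <- as.integer(names(support))[seq_len(min(length(support),
                                                   policy$max_candidates))]
    for (sj in cand) {
      ss <- seeds[seeds$subject == sj, , drop = FALSE]
      diag_lo <- min(ss$pos - ss$qstart)
      diag_hi <- max(ss$pos - ss$qstart)
      window <- c(max(1L, diag_lo + 1L - 25L),
                  min(nchar(index$sequences[sj]), diag_hi + m + 25L))
      ext <- extend_candidate(q, index$sequences[sj], window)
      if (is.null(ext)) next
      ka <- alignment_evalue(ext$score, m, index$total_length)
      out[[length(out) + 1L]] <- tibble(
        subject_id = index$ids[sj],
        subject_species = index$labels[sj],
        percent_identity = ext$identity,
        alignment_length = ext$length,
        mismatch = ext$mismatch,
        gapopen = ext$gapopen,
        qstart = ext$qstart, qend = ext$qend,
        sstart = ext$sstart, send = ext$send,
        bit_score = ka$bit_score,
        e_value = ka$e_value,
        strand = strand
      )
    }
  }
  if (!length(out)) return(NULL)
  dplyr::bind_rows(out)
}

#' Best hits for a set of queries
#'
#' Vectorised [best_hit()]: one row per query, `NA` fields where no hit
#' satisfied the policy.
#'
#' @param queries A fragment tibble.
#' @inheritParams best_hit
#' @return A tibble with `id`, `subject_id`, `subject_species`,
#'   `percent_identity`, `alignment_length`, `bit_score`, `e_value`.
#' @export
align_best_hits <- function(queries, index, policy = fallback_policy()) {
  queries <- as_fragments(queries)
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    h <- best_hit(queries$sequence[i], index, policy)
    if (is.null(h)) {
      tibble(id = queries$id[i], subject_id = NA_character_,
             subject_species = NA_character_,
             percent_identity = NA_real_, alignment_length = NA_integer_,
             bit_score = NA_real_, e_value = NA_real_)
    } else {
      dplyr::bind_cols(tibble(id = queries$id[i]),
                       h[, c("subject_id", "subject_species",
                             "percent_identity", "alignment_length",
                             "bit_score", "e_value")])
    }
  })
  dplyr::bind_rows(rows)
}

#' Read 12-column tabular alignment output
#'
#' Parses the standard 12-column tab-separated alignment format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore) as produced by `blastn -outfmt 6`, for the
#' external-tabular fallback mode.
#'
#' @param path Path to the tabular file.
#' @return A tibble with the 12 standard columns.
#' @export
read_alignment_tab <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore"),
    col_types = "ccdiiiiiiidd", progress = FALSE
  )
}

#' Best hit per query from tabular alignment records
#'
#' Applies the same acceptance policy and tie rules as the internal
#' aligner (lowest e-value, then highest bit score, then lowest subject
#' id) to externally produced 12-column records.
#'
#' @param hits A tibble as from [read_alignment_tab()].
#' @param labels Named character vector or `id`/`label` data frame
#'   mapping subject ids to species.
#' @inheritParams best_hit
#' @return A tibble `id`, `subject_id`, `subject_species`,
#'   `percent_identity`, `bit_score`, `e_value`, one row per query id
#'   present in `hits` whose best hit passes the policy.
#' @export
best_hits_tabular <- function(hits, labels, policy = fallback_policy()) {
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  hits <- hits[hits$evalue <= policy$e_value_cutoff, , drop = FALSE]
  if (!is.na(policy$min_identity)) {
    hits <- hits[hits$pident >= policy$min_identity, , drop = FALSE]
  }
  hits |>
    dplyr::arrange(.data$qseqid, .data$evalue, dplyr::desc(.data$bitscore),
                   .data$sseqid) |>
    dplyr::distinct(.data$qseqid, .keep_all = TRUE) |>
    dplyr::transmute(
      id = .data$qseqid,
      subject_id = .data$sseqid,
      subject_species = unname(labels[.data$sseqid]),
      percent_identity = .data$pident,
      bit_score = .data$bitscore,
      e_value = .data$evalue
    )
}
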