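# k-mer profiles: sparse count vectors over the 4^k word space.
#
# Index convention (fixed; model files depend on it): A=0, C=1, G=2, T=3,
# most-significant position first, so index(w) = sum_i digit(w_i) * 4^(k-i).
# This matches the column order of Biostrings::oligonucleotideFrequency.

# lookup from ASCII code to base digit; lowercase handled for robustness
# even though ingest uppercases. Anything else (incl. N) maps to NA.
.base_lut <- local({
  lut <- rep(NA_integer_, 128)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut
})

seq_to_digits <- function(sequence) {
  .base_lut[utf8ToInt(sequence)]
}

digits_to_seq <- function(d) {
  intToUtf8(c(65L, 67L, 71L, 84L)[d + 1L])
}

# base-4 rolling codes of all length-k windows; NA where a window touches
# a non-ACGT base. Integer-safe for k <= 15 (4^15 < 2^31).
rolling_codes <- function(digits, k) {
  m <- length(digits) - k + 1L
  if (m <= 0L) return(integer(0))
  code <- digits[seq_len(m)]
  if (k > 1L) {
    for (j in 2:k) code <- code * 4L + digits[j:(m + j - 1L)]
  }
  code
}

check_k <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k)) {
    abort("`k` must be a single positive integer.")
  }
  if (k > 15) abort("`k` above 15 overflows the integer k-mer index space.")
  as.integer(k)
}

#' Encode k-mer words as integer indices
#'
#' Maps words over \{A,C,G,T\} to their index in the 4^k-dimensional
#' profile vector under the fixed convention A=0, C=1, G=2, T=3 with the
#' first position most significant (so "AA.." is 0 and "TT.." is 4^k-1).
#' The map is a bijection between the 4^k words and `0:(4^k - 1)`.
#'
#' @param words Character vector of equal-length k-mer words.
#' @return Integer vector of indices in `[0, 4^k)`.
#' @seealso [decode_kmer()] for the inverse.
#' @examples
#' encode_kmer(c("AA", "TT"))
#' decode_kmer(0:3, k = 1)
#' @export
encode_kmer <- function(words) {
  k <- unique(nchar(words))
  if (length(k) != 1) abort("All words must have the same length.")
  k <- check_k(k)
  vapply(words, function(w) {
    d <- seq_to_digits(w)
    if (anyNA(d)) {
      p <- which(is.na(d))[1]
      abort(sprintf("Non-ACGT character '%s' at position %d of word '%s'.",
                    substr(w, p, p), p, w))
    }
    rolling_codes(d, k)
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname encode_kmer
#' @param index Integer vector of k-mer indices in `[0, 4^k)`.
#' @param k Word length.
#' @export
decode_kmer <- function(index, k) {
  k <- check_k(k)
  if (any(index < 0 | index >= 4^k)) abort("Index out of [0, 4^k).")
  vapply(index, function(i) {
    d <- integer(k)
    for (j in k:1) {
      d[j] <- i %% 4L
      i <- i %/% 4L
    }
    digits_to_seq(d)
  }, character(1))
}

#' Count k-mers in a single sequence
#'
#' Slides a length-`k` window along the given strand with step 1 and
#' tallies each A/C/G/T word; windows containing any other character
#' (e.g. N) are skipped entirely. For an ACGT-only sequence of length l
#' the counts sum to l - k + 1; a sequence shorter than k yields an empty
#' (all-zero) profile.
#'
#' @param sequence A single nucleotide sequence (A/C/G/T/N; lowercase
#'   tolerated).
#' @param k Word length.
#' @param canonical If `TRUE`, each window is counted as the
#'   lexicographically smaller of the word and its reverse complement.
#'   Off by default: profiles are strand-specific.
#' @return A tibble with columns `kmer`, `index` and `count`, one row per
#'   k-mer observed, sorted by `index`.
#' @examples
#' count_kmers("AAAA", 2)
#' count_kmers("ACGNACG", 3) # windows overlapping the N are skipped
#' @export
count_kmers <- function(sequence, k, canonical = FALSE) {
  stopifnot(length(sequence) == 1)
  k <- check_k(k)
  codes <- window_codes(seq_to_digits(toupper(sequence)), k, canonical)
  codes <- codes[!is.na(codes)]
  tab <- table(codes)
  idx <- as.integer(names(tab))
  tibble(
    kmer = if (length(idx)) decode_kmer(idx, k) else character(0),
    index = idx,
    count = as.integer(tab)
  )
}

# rolling codes with optional canonicalisation (min of word, revcomp word)
window_codes <- function(digits, k, canonical = FALSE) {
  code <- rolling_codes(digits, k)
  if (canonical && length(code)) {
    rc <- rolling_codes(rev(3L - digits), k)
    code <- pmin(code, rev(rc))
  }
  code
}

#' Sparse k-mer design matrix for a fragment table
#'
#' Converts fragments into the rows of a sparse count matrix over the
#' 4^k k-mer space: row i is the profile of fragment i (row order
#' preserved, row names = ids), column j+1 counts the word with index j.
#' Each fragment of length l contributes at most min(4^k, l - k + 1)
#' non-zero entries, so the matrix stays sparse even at k = 10
#' (4^10 = 1,048,576 columns). Values are raw integer counts unless
#' `normalize` is set.
#'
#' @param fragments A fragment tibble (see [as_fragments()]).
#' @inheritParams count_kmers
#' @param normalize If `TRUE`, divide each row by its number of valid
#'   windows (length normalisation). Off by default: the classifier is
#'   trained on raw counts.
#' @return A `dgCMatrix` with `nrow(fragments)` rows and 4^k columns.
#' @examples
#' frags <- as_fragments(c(a = "ACGTACGT", b = "ACGTACGT"))
#' dim(kmer_profiles(frags, k = 3))
#' @export
kmer_profiles <- function(fragments, k, canonical = FALSE, normalize = FALSE) {
  fragments <- as_fragments(fragments)
  k <- check_k(k)
  codes <- lapply(fragments$sequence,
                  function(s) window_codes(seq_to_digits(s), k, canonical))
  row <- rep.int(seq_along(codes), lengths(codes))
  j <- unlist(codes, use.names = FALSE)
  keep <- !is.na(j)
  m <- Matrix::sparseMatrix(
    i = row[keep], j = j[keep] + 1L, x = 1,
    dims = c(nrow(fragments), 4^k),
    dimnames = list(fragments$id, NULL)
  )
  if (normalize) {
    tot <- Matrix::rowSums(m)
    tot[tot == 0] <- 1
    m <- as(Matrix::Diagonal(x = 1 / tot) %*% m, "CsparseMatrix")
    dimnames(m) <- list(fragments$id, NULL)
  }
  m
}
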