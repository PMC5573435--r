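# The k-mer ensemble: one linear SVM per k-mer size, majority voting,
# and the confident/diffident partition of query fragments.

#' Train a k-mer ensemble of linear SVMs
#'
#' Trains one one-vs-rest L2-loss linear SVM per k-mer size in `kset` on
#' the labelled reference fragments (each member sees the same fragments
#' through its own 4^k-dimensional count profile). All members share the
#' same lexicographic class order and the same loss weight `omega`. The
#' members are independent of one another, so the trained ensemble does
#' not depend on the order in which they are fitted.
#'
#' @param reference A fragment tibble with a `label` column (species per
#'   fragment); at least 2 species.
#' @param kset Strictly increasing integer vector of k-mer sizes
#'   (default 6:10).
#' @param omega Positive loss weight shared by all members (default 32).
#' @param canonical,normalize Passed to [kmer_profiles()].
#' @param tol,max_iter Solver controls, see [svm_train_binary()].
#' @return An object of class `kmer_ensemble`: list with `kset`,
#'   `members` (one `svm_ovr` per k), `classes`, `omega`.
#' @examples
#' \donttest{
#' ds <- make_dataset(synthetic_spec(n_species = 3, genome_length = 4000,
#'                                   genomes_per_species = 2, seed = 1))
#' ens <- train_ensemble(ds$reference_fragments, kset = c(4, 5, 6))
#' ens
#' }
#' @export
train_ensemble <- function(reference, kset = 6:10, omega = 32,
                           canonical = FALSE, normalize = FALSE,
                           tol = 1e-3, max_iter = 1000) {
  reference <- as_fragments(reference)
  if (!"label" %in% names(reference) || anyNA(reference$label)) {
    abort("Every reference fragment needs a species `label`.")
  }
  kset <- vapply(kset, check_k, integer(1))
  if (!length(kset) || is.unsorted(kset, strictly = TRUE)) {
    abort("`kset` must be a non-empty, strictly increasing set of k values.")
  }
  members <- lapply(kset, function(k) {
    X <- kmer_profiles(reference, k, canonical = canonical,
                       normalize = normalize)
    svm_train_ovr(X, reference$label, omega = omega, k = k,
                  tol = tol, max_iter = max_iter)
  })
  names(members) <- paste0("k", kset)
  structure(
    list(kset = kset, members = members, classes = members[[1]]$classes,
         omega = omega, canonical = canonical, normalize = normalize),
    class = "kmer_ensemble"
  )
}

#' @export
print.kmer_ensemble <- function(x, ...) {
  cat(sprintf("k-mer SVM ensemble: k in {%s}, %d species, omega = %g\n",
              paste(x$kset, collapse = ", "), length(x$classes), x$omega))
  invisible(x)
}

#' Per-member predictions of the ensemble
#'
#' @param object A `kmer_ensemble`.
#' @param queries A fragment tibble.
#' @param ... Unused.
#' @return A character matrix, rows = fragments, one column per member
#'   (named `k6` ... per `kset`).
#' @export
predict_members <- function(object, queries, ...) {
  queries <- as_fragments(queries)
  preds <- vapply(object$members, function(m) {
    X <- kmer_profiles(queries, m$k, canonical = object$canonical,
                       normalize = object$normalize)
    predict(m, X)
  }, character(nrow(queries)))
  preds <- matrix(preds, nrow = nrow(queries),
                  dimnames = list(queries$id, names(object$members)))
  preds
}

#' Partition query fragments into confident and diffident sets
#'
#' Each member SVM votes a species for every query fragment. The
#' plurality label is the most frequent vote (ties broken towards the
#' class earliest in the model's class order) and the agreement count is
#' its frequency. A fragment is tagged `confident` when the agreement
#' count reaches the voting threshold, otherwise `diffident`; the two
#' sets are disjoint and cover all queries.
#'
#' @inheritParams predict_members
#' @param threshold Voting threshold, an integer in `[1, length(kset)]`;
#'   default full agreement (all members).
#' @return A `vote_partition` tibble: `id`, one vote column per member
#'   (`k6`, ...), `plurality`, `agreement`, `set` (factor
#'   confident/diffident).
#' @examples
#' \dontrun{
#' part <- vote_partition(ens, queries, threshold = 5)
#' dplyr::count(part, set)
#' }
#' @export
vote_partition <- function(object, queries, threshold = length(object$kset)) {
  check_threshold(threshold, length(object$kset))
  queries <- as_fragments(queries)
  votes <- predict_members(object, queries)
  tal <- tally_votes(votes, object$classes)
  out <- tibble(id = queries$id)
  out <- dplyr::bind_cols(out, as_tibble(votes))
  out$plurality <- tal$plurality
  out$agreement <- tal$agreement
  out$set <- factor(ifelse(tal$agreement >= threshold, "confident", "diffident"),
                    levels = c("confident", "diffident"))
  attr(out, "threshold") <- threshold
  attr(out, "kset") <- object$kset
  class(out) <- c("vote_partition", class(out))
  out
}

check_threshold <- function(threshold, n_members) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold < 1 || threshold > n_members ||
      threshold != as.integer(threshold)) {
    abort(sprintf("`threshold` must be an integer in [1, %d].", n_members))
  }
}

# plurality label and agreement count per row of a vote matrix;
# ties go to the class with the lowest index in `classes`.
tally_votes <- function(votes, classes) {
  idx <- matrix(match(votes, classes), nrow = nrow(votes))
  counts <- t(apply(idx, 1, tabulate, nbins = length(classes)))
  if (nrow(votes) == 1) counts <- matrix(counts, nrow = 1)
  best <- max.col(counts, ties.method = "first")
  list(plurality = classes[best],
       agreement = counts[cbind(seq_len(nrow(counts)), best)])
}

#' Classify fragments with the ensemble (voting stage only)
#'
#' Assigns every query its plurality label: confident fragments get the
#' label the members agreed on, diffident fragments get their plurality
#' label as well (the simplest deterministic rule for a voting-only
#' classifier). Use [classify_fragments()] with a reference to replace
#' diffident labels by alignment best hits.
#'
#' @inheritParams vote_partition
#' @return A tibble `id`, `label`, `set`, `agreement`; the full partition
#'   is attached as attribute `partition`.
#' @export
classify_vote <- function(object, queries, threshold = length(object$kset)) {
  part <- vote_partition(object, queries, threshold)
  out <- tibble(id = part$id, label = part$plurality,
                set = part$set, agreement = part$agreement)
  attr(out, "partition") <- part
  out
}

#' @describeIn train_ensemble `tidy()` method: one row per member.
#' @param x A `kmer_ensemble`.
#' @export
tidy.kmer_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(x$members, glance))
}

#' @describeIn train_ensemble `glance()` method: one-row summary.
#' @export
glance.kmer_ensemble <- function(x, ...) {
  tibble(
    n_members = length(x$members),
    k_min = min(x$kset), k_max = max(x$kset),
    n_classes = length(x$classes),
    omega = x$omega
  )
}

#' Save / load an ensemble model
#'
#' The on-disk container is versioned; predictions after a round trip are
#' identical to the in-memory model's.
#'
#' @param object A `kmer_ensemble`.
#' @param path File path.
#' @return `path` (write) or the restored `kmer_ensemble` (read).
#' @export
write_ensemble <- function(object, path) {
  stopifnot(inherits(object, "kmer_ensemble"))
  saveRDS(list(container = "kmervote_ensemble", version = 1L, model = object),
          path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  x <- readRDS(path)
  if (!identical(x$container, "kmervote_ensemble")) {
    abort(sprintf("'%s' is not an ensemble model container.", path))
  }
  x$model
}
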