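# The full two-stage classifier: ensemble vote, then best-hit alignment
# fallback on the diffident set only. Confident labels are never touched
# by the fallback.

#' Classify fragments with voting and an alignment fallback
#'
#' Stage 1 votes every query with the ensemble and partitions it into
#' confident/diffident sets at the given threshold. Stage 2 reclassifies
#' only the diffident fragments by their best local-alignment hit against
#' the reference set; a diffident fragment with no acceptable hit is
#' tagged `"unknown"`. Confident fragments keep their stage-1 labels
#' bitwise - the fallback cannot change them.
#'
#' The reference can be given as a fragment tibble (indexed internally)
#' or as a prebuilt [build_reference_index()]. Alternatively,
#' `tabular_hits` supplies externally computed 12-column alignment
#' records (e.g. from `blastn -outfmt 6` of the diffident fragments
#' against the same reference), which are filtered by the same policy
#' and tie rules.
#'
#' @inheritParams vote_partition
#' @param reference Reference sequences with `label`s, or a
#'   `reference_index`. Ignored when `tabular_hits` is given.
#' @param policy A [fallback_policy()].
#' @param tabular_hits Optional tibble from [read_alignment_tab()]
#'   (external-tabular fallback mode); requires `reference` as a
#'   labelled tibble or a `labels` mapping in `...` is not supported -
#'   subject ids are looked up in `reference`.
#' @return A tibble `id`, `label` (species or `"unknown"`), `set`,
#'   `agreement`, `method` (`vote` / `alignment` / `unknown`),
#'   `e_value`, `percent_identity`; the stage-1 partition is attached as
#'   attribute `partition`.
#' @examples
#' \dontrun{
#' res <- classify_fragments(ens, queries, reference = ref, threshold = 5)
#' dplyr::count(res, set, method)
#' }
#' @export
classify_fragments <- function(object, queries,
                               reference = NULL,
                               threshold = length(object$kset),
                               policy = fallback_policy(),
                               tabular_hits = NULL) {
  part <- vote_partition(object, queries, threshold)
  out <- tibble(
    id = part$id, label = part$plurality, set = part$set,
    agreement = part$agreement,
    method = "vote", e_value = NA_real_, percent_identity = NA_real_
  )
  diffident <- out$set == "diffident"
  if (any(diffident) && (!is.null(reference) || !is.null(tabular_hits))) {
    queries <- as_fragments(queries)
    dq <- queries[match(out$id[diffident], queries$id), , drop = FALSE]
    if (!is.null(tabular_hits)) {
      labels <- reference_labels(reference)
      bh <- best_hits_tabular(tabular_hits, labels, policy)
      hits <- dplyr::left_join(tibble(id = dq$id), bh, by = "id")
    } else {
      index <- if (inherits(reference, "reference_index")) reference
               else build_reference_index(reference, word_size = policy$word_size)
      hits <- align_best_hits(dq, index, policy)
    }
    found <- !is.na(hits$subject_species)
    out$label[diffident] <- ifelse(found, hits$subject_species, "unknown")
    out$method[diffident] <- ifelse(found, "alignment", "unknown")
    out$e_value[diffident] <- hits$e_value
    out$percent_identity[diffident] <- hits$percent_identity
  }
  attr(out, "partition") <- part
  class(out) <- c("fragment_classification", class(out))
  out
}

reference_labels <- function(reference) {
  if (inherits(reference, "reference_index")) {
    setNames(reference$labels, reference$ids)
  } else if (is.data.frame(reference)) {
    setNames(reference$label, reference$id)
  } else {
    abort("`reference` (with labels) is required for tabular fallback mode.")
  }
}

#' Sweep voting thresholds
#'
#' Re-partitions and re-evaluates a query set at each voting threshold,
#' reusing a single trained ensemble and (when a reference is given) a
#' single alignment pass per threshold. Useful to study the trade-off
#' between confident-set size and staged accuracy.
#'
#' @inheritParams classify_fragments
#' @param thresholds Integer vector of thresholds to evaluate.
#' @param truth Tibble `id`, `label` with ground truth.
#' @return A tibble: one row per threshold x stage with the report
#'   columns plus `threshold` and `n_confident`.
#' @export
sweep_thresholds <- function(object, queries, truth,
                             thresholds = seq_along(object$kset),
                             reference = NULL,
                             policy = fallback_policy()) {
  index <- if (!is.null(reference) && !inherits(reference, "reference_index")) {
    build_reference_index(reference, word_size = policy$word_size)
  } else {
    reference
  }
  purrr::map_dfr(thresholds, function(t) {
    res <- classify_fragments(object, queries, reference = index,
                              threshold = t, policy = policy)
    rep <- staged_report(res, truth)
    rep$threshold <- t
    rep$n_confident <- sum(res$set == "confident")
    rep
  })
}
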