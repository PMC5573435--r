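# Staged evaluation: per-class confusion counts and the aggregate
# accuracy / sensitivity / specificity / true-positive reports.
#
# Conventions (both are reported rather than silently chosen):
# * accuracy = 100 * total true positives / n_total, where n_total is
#   the number of fragments in the validation set INCLUDING the ones
#   tagged unknown - a method is not rewarded for refusing to answer;
# * sensitivity / specificity are macro-averages over classes (micro
#   available), computed over the evaluated (non-unknown) fragments.

#' Per-class confusion counts for multiclass predictions
#'
#' One-vs-rest confusion per class: TP (predicted c, truth c), FP
#' (predicted c, truth not c), FN (truth c, predicted other), TN (the
#' rest), over the evaluated fragments. When `exclude_unknown` is set
#' (the default), fragments predicted `"unknown"` are removed from every
#' denominator and only counted in the `n_unknown` attribute.
#'
#' @param truth Character vector of true species labels.
#' @param estimate Character vector of predicted labels, possibly
#'   containing `"unknown"`; same length and order as `truth`.
#' @param exclude_unknown Drop `"unknown"` predictions from the confusion
#'   (default `TRUE`).
#' @return A tibble `class`, `tp`, `fp`, `fn`, `tn` with attributes
#'   `n_total`, `n_evaluated`, `n_unknown`.
#' @examples
#' confusion_counts(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusion_counts <- function(truth, estimate, exclude_unknown = TRUE) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must be aligned (same length and order).")
  }
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  n_total <- length(truth)
  unk <- estimate == "unknown"
  if (exclude_unknown) {
    truth_e <- truth[!unk]
    est_e <- estimate[!unk]
  } else {
    truth_e <- truth
    est_e <- estimate
  }
  classes <- sort(union(truth, setdiff(estimate, "unknown")), method = "radix")
  n_eval <- length(truth_e)
  out <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(est_e == cl & truth_e == cl)
    fp <- sum(est_e == cl & truth_e != cl)
    fn <- sum(truth_e == cl & est_e != cl)
    tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = n_eval - tp - fp - fn)
  })
  attr(out, "n_total") <- n_total
  attr(out, "n_evaluated") <- n_eval
  attr(out, "n_unknown") <- sum(unk)
  out
}

#' Aggregate classification report
#'
#' Computes the headline metrics from per-class confusion counts:
#' * `accuracy` = 100 * sum(TP) / `n_total` - the denominator is every
#'   fragment in the validation set, so unknowns count against accuracy;
#' * `sensitivity` = average of per-class TP/(TP+FN) (x100);
#' * `specificity` = average of per-class TN/(TN+FP) (x100);
#' with macro (per-class mean, classes with an empty denominator
#' skipped) or micro (pooled counts) averaging.
#'
#' @param confusion A tibble from [confusion_counts()].
#' @param n_total Number of fragments in the validation set (defaults to
#'   the attribute recorded by [confusion_counts()]).
#' @param average `"macro"` (default) or `"micro"`.
#' @return A one-row tibble: `n_total`, `n_evaluated`, `n_unknown`,
#'   `true_positives`, `accuracy`, `sensitivity`, `specificity`,
#'   `average`. Metrics are `NA` when nothing was evaluated.
#' @examples
#' cm <- confusion_counts(rep(c("a", "b", "c"), 10), rep(c("a", "b", "c"), 10))
#' classification_report(cm)
#' @export
classification_report <- function(confusion, n_total = NULL,
                                  average = c("macro", "micro")) {
  average <- match.arg(average)
  if (is.null(n_total)) n_total <- attr(confusion, "n_total")
  if (is.null(n_total)) abort("`n_total` is required.")
  if (n_total == 0) abort("`n_total` must be positive.")
  n_eval <- attr(confusion, "n_evaluated") %||% sum(confusion$tp + confusion$fn)
  n_unknown <- attr(confusion, "n_unknown") %||% 0L
  tp_total <- sum(confusion$tp)
  if (n_eval == 0) {
    sens <- spec <- NA_real_
  } else if (average == "macro") {
    se <- with(confusion, ifelse(tp + fn > 0, tp / (tp + fn), NA_real_))
    sp <- with(confusion, ifelse(tn + fp > 0, tn / (tn + fp), NA_real_))
    sens <- 100 * mean(se, na.rm = TRUE)
    spec <- 100 * mean(sp, na.rm = TRUE)
  } else {
    sens <- 100 * sum(confusion$tp) / sum(confusion$tp + confusion$fn)
    spec <- 100 * sum(confusion$tn) / sum(confusion$tn + confusion$fp)
  }
  tibble(
    n_total = as.integer(n_total),
    n_evaluated = as.integer(n_eval),
    n_unknown = as.integer(n_unknown),
    true_positives = as.integer(tp_total),
    accuracy = if (n_eval == 0) NA_real_ else 100 * tp_total / n_total,
    sensitivity = sens,
    specificity = spec,
    average = average
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate predictions against truth by fragment id
#'
#' Joins predictions to truth on `id` (every predicted id must have a
#' truth label) and produces a [classification_report()].
#'
#' @param predictions Tibble with `id` and `label` (possibly
#'   `"unknown"`).
#' @param truth Tibble with `id` and `label` (true species), or a named
#'   character vector.
#' @inheritParams classification_report
#' @inheritParams confusion_counts
#' @return A one-row report tibble.
#' @export
evaluate_predictions <- function(predictions, truth,
                                 average = c("macro", "micro"),
                                 exclude_unknown = TRUE) {
  pt <- join_truth(predictions, truth)
  cm <- confusion_counts(pt$truth, pt$label, exclude_unknown = exclude_unknown)
  classification_report(cm, average = match.arg(average))
}

join_truth <- function(predictions, truth) {
  if (!is.data.frame(truth)) truth <- tibble(id = names(truth), label = unname(truth))
  missing <- setdiff(predictions$id, truth$id)
  if (length(missing)) {
    abort(paste0("No truth label for id(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  dplyr::left_join(predictions,
                   dplyr::rename(truth[, c("id", "label")], truth = "label"),
                   by = "id")
}

#' Staged report: confident set, diffident set, combined
#'
#' Evaluates a classified query set separately on the confident set, the
#' diffident set, and combined, mirroring the staged reporting of the
#' two-stage classifier. Accuracy in each row uses that row's set size
#' as denominator (the combined row's denominator is the whole
#' validation set).
#'
#' @param classified Tibble with `id`, `label` and `set` columns (as
#'   from [classify_vote()] or [classify_fragments()]).
#' @param truth Tibble with `id`, `label`, or a named character vector.
#' @inheritParams classification_report
#' @return A `staged_report` tibble with a `stage` column
#'   (confident / diffident / combined) and the report columns; stages
#'   with no fragments have `n_total = 0` and `NA` metrics.
#' @export
staged_report <- function(classified, truth, average = c("macro", "micro")) {
  average <- match.arg(average)
  pt <- join_truth(classified, truth)
  one <- function(d, stage) {
    if (!nrow(d)) {
      return(tibble(stage = stage, n_total = 0L, n_evaluated = 0L,
                    n_unknown = 0L, true_positives = 0L,
                    accuracy = NA_real_, sensitivity = NA_real_,
                    specificity = NA_real_, average = average))
    }
    cm <- confusion_counts(d$truth, d$label)
    dplyr::bind_cols(tibble(stage = stage),
                     classification_report(cm, average = average))
  }
  out <- dplyr::bind_rows(
    one(pt[pt$set == "confident", , drop = FALSE], "confident"),
    one(pt[pt$set == "diffident", , drop = FALSE], "diffident"),
    one(pt, "combined")
  )
  class(out) <- c("staged_report", class(out))
  out
}

#' Map species labels to a higher taxonomic level
#'
#' Re-labels predictions and truth through a species-to-level mapping
#' (e.g. species to phylum) so the same reports can be produced at
#' coarser levels. Labels without a mapping are kept unchanged;
#' `"unknown"` is always kept.
#'
#' @param labels Character vector of species labels.
#' @param mapping Two-column data frame (`species`, `level`) or named
#'   character vector.
#' @return Character vector of re-mapped labels.
#' @export
map_taxonomy <- function(labels, mapping) {
  if (is.data.frame(mapping)) {
    mapping <- setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
  }
  out <- unname(mapping[labels])
  ifelse(is.na(out), labels, out)
}
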