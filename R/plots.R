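# ggplot2 views of the result types.

#' Plot the vote-agreement distribution of a partition
#'
#' Bar chart of the maximum agreement count per fragment, coloured by
#' confident/diffident set tag; the voting threshold used for the
#' partition is drawn as a dashed line.
#'
#' @param object A [vote_partition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vote_partition <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$agreement, fill = .data$set)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = thr - 0.5, linetype = "dashed") +
    ggplot2::labs(x = "ensemble agreement (votes for plurality label)",
                  y = "fragments", fill = NULL,
                  title = sprintf("Vote partition at threshold %d", thr)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vote_partition
#' @export
plot_vote_agreement <- function(object, ...) autoplot.vote_partition(object, ...)

#' Plot a staged report
#'
#' Grouped bars of accuracy / sensitivity / specificity for the
#' confident, diffident and combined stages.
#'
#' @param object A [staged_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staged_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("stage", "accuracy", "sensitivity", "specificity")],
    -"stage", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "%", fill = NULL,
                  title = "Staged classification performance") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.staged_report
#' @export
plot_staged_report <- function(object, ...) autoplot.staged_report(object, ...)

#' Plot a voting-threshold sweep
#'
#' Combined-stage accuracy (and confident-set fraction) as a function of
#' the voting threshold, from [sweep_thresholds()] output.
#'
#' @param sweep A tibble from [sweep_thresholds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep, ...) {
  comb <- sweep[sweep$stage == "combined", , drop = FALSE]
  comb$confident_fraction <- 100 * comb$n_confident / comb$n_total
  long <- tidyr::pivot_longer(
    comb[, c("threshold", "accuracy", "confident_fraction")],
    -"threshold", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "voting threshold", y = "%", colour = NULL,
                  title = "Voting-threshold sweep") +
    ggplot2::theme_minimal()
}
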