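# confusion counts, reports, staged reports

# hand-built 3-class confusion: A->A 8, A->B 2, B->B 9, B->C 1, C->C 10
hand_truth <- rep(c("A", "B", "C"), each = 10)
hand_pred <- c(rep("A", 8), rep("B", 2), rep("B", 9), "C", rep("C", 10))

test_that("confusion counts match a by-hand tally", {
  cm <- confusion_counts(hand_truth, hand_pred)
  expect_identical(cm$class, c("A", "B", "C"))
  expect_identical(cm$tp, c(8L, 9L, 10L))
  expect_identical(cm$fp, c(0L, 2L, 1L))
  expect_identical(cm$fn, c(2L, 1L, 0L))
  expect_identical(cm$tn, c(20L, 18L, 19L))
  # per class: TP + FP + FN + TN = evaluated fragments
  expect_true(all(cm$tp + cm$fp + cm$fn + cm$tn == 30L))
})

test_that("report arithmetic: 27/30 correct gives 90% accuracy", {
  cm <- confusion_counts(hand_truth, hand_pred)
  rep <- classification_report(cm)
  expect_equal(rep$accuracy, 100 * 27 / 30)
  expect_identical(rep$true_positives, 27L)
  # macro sensitivity = mean(8/10, 9/10, 10/10)
  expect_equal(rep$sensitivity, 100 * mean(c(0.8, 0.9, 1.0)))
  expect_equal(rep$specificity, 100 * mean(c(20 / 20, 18 / 20, 19 / 20)))
})

test_that("perfect and single-fragment predictions give 100%", {
  cm <- confusion_counts(rep(c("a", "b", "c"), 10), rep(c("a", "b", "c"), 10))
  rep <- classification_report(cm)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100)
  expect_identical(rep$true_positives, 30L)
  one <- classification_report(confusion_counts("a", "a"))
  expect_equal(one$accuracy, 100)
  expect_identical(one$true_positives, 1L)
})

test_that("unknown predictions leave denominators but count against accuracy", {
  truth <- c("a", "a", "b", "b")
  pred <- c("a", "unknown", "b", "unknown")
  cm <- confusion_counts(truth, pred)
  expect_identical(attr(cm, "n_unknown"), 2L)
  expect_identical(attr(cm, "n_evaluated"), 2L)
  rep <- classification_report(cm)
  # accuracy keeps the full denominator: 2 TP / 4 fragments
  expect_equal(rep$accuracy, 50)
  # sensitivity/specificity are over evaluated fragments only: perfect here
  expect_equal(rep$sensitivity, 100)
  # everything unknown: metrics not applicable
  cm2 <- confusion_counts(truth, rep("unknown", 4))
  rep2 <- classification_report(cm2)
  expect_identical(rep2$n_unknown, 4L)
  expect_true(is.na(rep2$accuracy) && is.na(rep2$sensitivity))
})

test_that("metrics are invariant under class renaming", {
  r1 <- classification_report(confusion_counts(hand_truth, hand_pred))
  ren <- c(A = "zeta", B = "eta", C = "theta")
  r2 <- classification_report(confusion_counts(ren[hand_truth], ren[hand_pred]))
  expect_equal(r1[, -ncol(r1)], r2[, -ncol(r2)])
})

test_that("evaluate_predictions joins by id and rejects missing truth", {
  pred <- tibble::tibble(id = c("f1", "f2"), label = c("a", "b"))
  truth <- tibble::tibble(id = c("f1", "f2"), label = c("a", "a"))
  rep <- evaluate_predictions(pred, truth)
  expect_equal(rep$accuracy, 50)
  expect_error(evaluate_predictions(pred, truth[1, ]), "f2")
})

test_that("staged reports split by set and recombine as a weighted mean", {
  classified <- tibble::tibble(
    id = sprintf("f%d", 1:10),
    label = c(rep("a", 6), "b", "b", "a", "b"),
    set = factor(c(rep("confident", 6), rep("diffident", 4)),
                 levels = c("confident", "diffident"))
  )
  truth <- tibble::tibble(id = classified$id,
                          label = c(rep("a", 6), "b", "a", "b", "a"))
  rep <- staged_report(classified, truth)
  expect_identical(rep$stage, c("confident", "diffident", "combined"))
  expect_identical(rep$n_total, c(6L, 4L, 10L))
  # combined accuracy is the set-size-weighted mean when nothing is unknown
  expect_equal(rep$accuracy[3],
               (rep$accuracy[1] * 6 + rep$accuracy[2] * 4) / 10)
  expect_true(rep$accuracy[3] >= min(rep$accuracy[1:2]) &&
                rep$accuracy[3] <= max(rep$accuracy[1:2]))
})

test_that("an empty diffident set is reported as not applicable", {
  classified <- tibble::tibble(id = c("f1", "f2"), label = c("a", "b"),
                               set = factor(c("confident", "confident"),
                                            levels = c("confident", "diffident")))
  truth <- tibble::tibble(id = c("f1", "f2"), label = c("a", "b"))
  rep <- staged_report(classified, truth)
  expect_identical(rep$n_total[rep$stage == "diffident"], 0L)
  expect_true(is.na(rep$accuracy[rep$stage == "diffident"]))
})

test_that("taxonomy mapping relabels for coarser-level reports", {
  mp <- tibble::tibble(species = c("a", "b"), level = c("P1", "P1"))
  expect_identical(map_taxonomy(c("a", "b", "unknown"), mp),
                   c("P1", "P1", "unknown"))
  # species-level mistakes inside one phylum become phylum-level hits
  pred <- tibble::tibble(id = c("f1", "f2"), label = c("a", "b"))
  truth <- tibble::tibble(id = c("f1", "f2"), label = c("b", "b"))
  sp <- evaluate_predictions(pred, truth)
  ph <- evaluate_predictions(dplyr::mutate(pred, label = map_taxonomy(label, mp)),
                             dplyr::mutate(truth, label = map_taxonomy(label, mp)))
  expect_lt(sp$accuracy, ph$accuracy)
  expect_equal(ph$accuracy, 100)
})
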