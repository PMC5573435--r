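# L2-loss linear SVMs, one-vs-rest, on sparse k-mer design matrices.
#
# The binary problem is min_W (1/2) W'W + omega * sum_j max(1 - W'x_j c_j, 0)^2
# with labels c_j in {-1,+1}; no bias term by default (the decision
# function is W'x through the origin, as is usual for high-dimensional
# count features). Solved by dual coordinate descent in C++.

#' Train a binary L2-loss linear SVM
#'
#' Minimises `(1/2) W'W + omega * sum_j max(1 - W'x_j c_j, 0)^2` by dual
#' coordinate descent, run until the projected-gradient gap falls below
#' `tol` (or `max_iter` passes). The solver is deterministic for a fixed
#' data ordering.
#'
#' @param X Design matrix (rows = points), dense or `dgCMatrix`.
#' @param y Numeric labels in \{-1, +1\}, one per row; both classes must
#'   be present.
#' @param omega Positive loss weight on constraint violations.
#' @param tol Convergence tolerance on the projected-gradient gap.
#' @param max_iter Maximum number of passes over the data.
#' @param bias If `TRUE`, augment features with a constant 1 column
#'   (trained bias). Off by default.
#' @return Numeric weight vector `W` (length `ncol(X)`, plus one if
#'   `bias`), with attributes `iter` and `converged`.
#' @examples
#' X <- rbind(c(1, 0), c(-1, 0))
#' w <- svm_train_binary(X, c(1, -1), omega = 32)
#' sign(X %*% w)
#' @export
svm_train_binary <- function(X, y, omega, tol = 1e-3, max_iter = 1000,
                             bias = FALSE) {
  if (length(omega) != 1 || !is.finite(omega) || omega <= 0) {
    abort("`omega` must be a single positive number.")
  }
  if (!all(y %in% c(-1, 1))) abort("`y` must contain only -1 and +1.")
  if (length(unique(y)) < 2) {
    abort("Both classes must be present in `y` to train a binary SVM.")
  }
  X <- as_dgc(X)
  if (bias) X <- cbind(X, 1)
  Xt <- Matrix::t(X)
  fit <- dcd_l2_svm(Xt@p, Xt@i, Xt@x, nrow(Xt), as.numeric(y),
                    omega, tol, as.integer(max_iter))
  w <- fit$w
  attr(w, "iter") <- fit$iter
  attr(w, "converged") <- fit$converged
  w
}

as_dgc <- function(X) {
  if (is(X, "dgCMatrix")) return(X)
  as(as(as(Matrix::Matrix(X, sparse = TRUE), "dMatrix"), "generalMatrix"),
     "CsparseMatrix")
}

#' Primal objective of the L2-loss SVM
#'
#' @inheritParams svm_train_binary
#' @param w Weight vector.
#' @return The value of `(1/2) w'w + omega * sum_j max(1 - w'x_j y_j, 0)^2`.
#' @export
svm_objective <- function(w, X, y, omega) {
  margin <- as.numeric(X %*% w) * y
  0.5 * sum(w^2) + omega * sum(pmax(1 - margin, 0)^2)
}

#' Train a one-vs-rest multiclass linear SVM
#'
#' Fits one binary L2-loss SVM per species: for class c the positive set
#' is the fragments labelled c and the negative set is everything else,
#' all with the same `omega`. Classes are ordered lexicographically
#' (C locale) and that order is fixed in the model. The binary problems
#' are independent, so the result does not depend on the order they are
#' solved in.
#'
#' @inheritParams svm_train_binary
#' @param labels Character vector of species labels, one per row of `X`
#'   (at least 2 distinct values).
#' @param k The k-mer size the design matrix was built with (recorded in
#'   the model; use `NA` for non-k-mer features).
#' @return An object of class `svm_ovr`: list with elements `k`,
#'   `classes`, `W` (feature x class weight matrix), `omega`, `bias`.
#' @examples
#' X <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
#' fit <- svm_train_ovr(X, c("a", "b", "c"), omega = 32)
#' predict(fit, X)
#' @export
svm_train_ovr <- function(X, labels, omega = 32, k = NA_integer_,
                          tol = 1e-3, max_iter = 1000, bias = FALSE) {
  labels <- as.character(labels)
  classes <- sort(unique(labels), method = "radix")
  if (length(classes) < 2) abort("Need at least 2 distinct species to train.")
  if (length(labels) != nrow(X)) abort("One label per row of `X` is required.")
  X <- as_dgc(X)
  W <- vapply(classes, function(cl) {
    yy <- ifelse(labels == cl, 1, -1)
    as.numeric(svm_train_binary(X, yy, omega, tol = tol,
                                max_iter = max_iter, bias = bias))
  }, numeric(ncol(X) + as.integer(bias)))
  structure(
    list(k = k, classes = classes, W = W, omega = omega, bias = bias),
    class = "svm_ovr"
  )
}

#' @export
print.svm_ovr <- function(x, ...) {
  cat(sprintf("One-vs-rest L2-loss linear SVM (k = %s)\n",
              ifelse(is.na(x$k), "?", x$k)))
  cat(sprintf("  %d classes, %d features, omega = %g\n",
              length(x$classes), nrow(x$W), x$omega))
  invisible(x)
}

#' Predict species with a one-vs-rest SVM
#'
#' The predicted label is the class with the largest decision value
#' `W_c' x`; exact ties go to the class with the lowest index (i.e. first
#' in lexicographic order).
#'
#' @param object An `svm_ovr` model.
#' @param newdata Design matrix with the same feature dimension the model
#'   was trained on, or a fragment tibble (profiled at the model's `k`).
#' @param type `"label"` (default) for predicted species, `"decision"`
#'   for the matrix of per-class decision values.
#' @param ... Unused.
#' @return Character vector of labels, or a numeric matrix.
#' @export
predict.svm_ovr <- function(object, newdata, type = c("label", "decision"),
                            ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    if (is.na(object$k)) abort("Model has no `k`; supply a design matrix.")
    newdata <- kmer_profiles(newdata, object$k)
  }
  d <- nrow(object$W) - as.integer(object$bias)
  if (ncol(newdata) != d) {
    abort(sprintf("Feature dimension mismatch: model has %d, data has %d.",
                  d, ncol(newdata)))
  }
  if (object$bias) newdata <- cbind(newdata, 1)
  scores <- as.matrix(newdata %*% object$W)
  colnames(scores) <- object$classes
  if (type == "decision") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Select omega by stratified cross-validation
#'
#' Evaluates each candidate loss weight by `folds`-fold stratified
#' cross-validated accuracy of the one-vs-rest SVM and returns the value
#' with the highest mean accuracy; ties go to the smallest omega. Fold
#' assignment is stratified within each class and drawn from `seed`, so
#' the selection is reproducible.
#'
#' @inheritParams svm_train_ovr
#' @param grid Numeric vector of candidate omega values.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return The selected omega, with the per-candidate mean accuracies in
#'   attribute `cv`.
#' @export
svm_select_omega <- function(X, labels, grid = c(1, 8, 32, 128),
                             folds = 5, seed = 1, k = NA_integer_,
                             tol = 1e-3, max_iter = 1000) {
  if (folds < 2) abort("`folds` must be at least 2.")
  if (!length(grid) || any(grid <= 0)) abort("`grid` must be positive.")
  labels <- as.character(labels)
  X <- as_dgc(X)
  n_class <- table(labels)
  if (any(n_class < folds)) {
    abort(sprintf("Class '%s' has fewer members (%d) than folds (%d).",
                  names(n_class)[which.min(n_class)], min(n_class), folds))
  }
  fold <- integer(length(labels))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  grid <- sort(grid)
  acc <- vapply(grid, function(om) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- svm_train_ovr(X[tr, , drop = FALSE], labels[tr], omega = om,
                           k = k, tol = tol, max_iter = max_iter)
      mean(predict(fit, X[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1)))
  }, numeric(1))
  best <- grid[which.max(acc)] # which.max takes the first (smallest) on ties
  attr(best, "cv") <- setNames(acc, grid)
  best
}

#' @describeIn svm_train_ovr `tidy()` method: one row per class with the
#'   weight-vector norm and sparsity.
#' @param x An `svm_ovr` object.
#' @export
tidy.svm_ovr <- function(x, ...) {
  tibble(
    class = x$classes,
    w_norm = sqrt(colSums(x$W^2)),
    n_nonzero = colSums(x$W != 0)
  )
}

#' @describeIn svm_train_ovr `glance()` method: one-row model summary.
#' @export
glance.svm_ovr <- function(x, ...) {
  tibble(
    k = x$k,
    n_classes = length(x$classes),
    n_features = nrow(x$W) - as.integer(x$bias),
    omega = x$omega,
    bias = x$bias
  )
}
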