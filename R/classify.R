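check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop_param("feature matrix contains non-finite values")
  if (nrow(x) != length(y)) stop_param("feature rows and labels differ in length")
  if (!all(y %in% c(-1, 1))) {
    stop_param("labels must be +1 (healthy/normal) or -1 (pathological)")
  }
  if (length(unique(y)) < 2) {
    stop_param("training requires both classes present")
  }
  x
}

#' Train a soft-margin linear SVM
#'
#' Maximum-margin linear classifier: the separating hyperplane `w'x - b = 0`
#' minimizing `|w|^2 / 2` subject to `y_i (w'x_i - b) >= 1` (soft-margin with
#' slack at finite `regularization`; the hard-margin solution is recovered as
#' the cost grows). Labels follow the convention `+1` = healthy/normal, `-1` =
#' pathological. Features are z-standardized internally and the scaling stored
#' so prediction is self-contained.
#'
#' @param x Feature matrix (recordings x features), finite.
#' @param y Labels in `{+1, -1}`, both classes present.
#' @param regularization Soft-margin cost C > 0; default 1.
#' @param standardize Standardize columns before fitting (default TRUE).
#' @return A `pcg_svm`: weights `w` and offset `b` (in the standardized
#'   space), per-feature `center`/`scale`, `margin` = 2/|w|.
#' @export
train_linear_svm <- function(x, y, regularization = 1, standardize = TRUE) {
  x <- check_xy(x, y)
  check_scalar(regularization, "regularization", positive = TRUE)
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0] <- 1
  } else {
    center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  fit <- e1071::svm(xs, factor(y, levels = c(-1, 1)), type = "C-classification",
                    kernel = "linear", cost = regularization, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- fit$rho
  # libsvm's sign convention depends on training-label order; orient so that
  # positive decision values mean class +1
  dv <- drop(xs %*% w) - b
  acc_pos <- mean(ifelse(dv >= 0, 1, -1) == y)
  acc_neg <- mean(ifelse(-dv >= 0, 1, -1) == y)
  if (acc_neg > acc_pos) { w <- -w; b <- -b }

  structure(list(w = w, b = b, center = center, scale = scale,
                 margin = 2 / sqrt(sum(w^2)),
                 regularization = regularization),
            class = "pcg_svm")
}

#' Predict with a trained linear SVM
#'
#' Applies the stored standardization, computes decision values
#' `w'x - b` and labels by their sign. A point exactly on the boundary
#' (decision value 0) is labeled `+1` (healthy) by convention.
#'
#' @param object A `pcg_svm` model.
#' @param newdata Feature matrix with the model's dimensionality.
#' @param ... Unused.
#' @return List with `labels` (`+1`/`-1`) and `decision_values`.
#' @export
predict.pcg_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$w)) {
    stop_param("feature dimensionality (", ncol(x), ") does not match model (",
               length(object$w), ")")
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  dv <- drop(xs %*% object$w) - object$b
  list(labels = ifelse(dv >= 0, 1, -1), decision_values = dv)
}

#' Confusion-matrix summary metrics
#'
#' @param confusion 2x2 non-negative counts, rows = actual, columns =
#'   predicted, order (normal, pathological).
#' @return List with `accuracy_percent` (100 x trace / total) and
#'   `per_class_percent` (100 x diagonal / row sums, named).
#' @export
confusion_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (!all(dim(cm) == c(2, 2)) || any(cm < 0)) {
    stop_param("`confusion` must be a 2x2 matrix of non-negative counts")
  }
  total <- sum(cm)
  if (total == 0) stop_param("confusion matrix is empty")
  list(accuracy_percent = 100 * sum(diag(cm)) / total,
       per_class_percent = c(normal = 100 * cm[1, 1] / sum(cm[1, ]),
                             pathological = 100 * cm[2, 2] / sum(cm[2, ])))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the sorted unique decision values
#' (positive class `+1`, higher values more positive), recording the
#' (false-positive rate, true-positive rate) at each, and integrates by the
#' trapezoidal rule. Tied values are grouped, which makes the AUC equal to
#' the pairwise concordance probability with half-credit for ties.
#'
#' @param decision_values Numeric scores.
#' @param labels Labels in `{+1, -1}`, both present.
#' @return List with `roc_points` (data frame `fpr`, `tpr`, `threshold`,
#'   from (0,0) to (1,1), both coordinates non-decreasing) and `auc`.
#' @export
roc_auc <- function(decision_values, labels) {
  if (length(decision_values) != length(labels)) {
    stop_param("scores and labels differ in length")
  }
  if (!all(labels %in% c(-1, 1)) || length(unique(labels)) < 2) {
    stop_param("labels must contain both +1 and -1")
  }
  n_pos <- sum(labels == 1); n_neg <- sum(labels == -1)
  th <- sort(unique(decision_values), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(decision_values >= t & labels == 1),
                numeric(1)) / n_pos
  fpr <- vapply(th, function(t) sum(decision_values >= t & labels == -1),
                numeric(1)) / n_neg
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, th, -Inf))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(roc_points = pts, auc = auc)
}

# Stratified fold assignment: within each class the (seeded) shuffled members
# are dealt round-robin, with the dealing position carried across classes so
# overall fold sizes differ by at most one.
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  folds <- integer(n)
  pos <- 0L
  with_seed(seed, {
    for (cls in c(1, -1)) {
      members <- which(y == cls)
      if (length(members) < k) {
        stop_param("each class needs at least k = ", k, " members; class ",
                   cls, " has ", length(members))
      }
      members <- sample(members)
      for (m in members) {
        folds[m] <- (pos %% k) + 1L
        pos <- pos + 1L
      }
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the linear SVM
#'
#' Splits the data into k stratified folds (seeded), trains on k-1 folds and
#' predicts the held-out fold, so each recording is predicted exactly once.
#' Standardization is fit inside each training fold only (no leakage). The
#' confusion matrix, accuracy, per-class percents, and a pooled
#' decision-value ROC/AUC are computed from the out-of-fold predictions.
#'
#' @param x Feature matrix (recordings x features).
#' @param y Labels in `{+1, -1}` (+1 = normal/healthy).
#' @param k Number of folds (>= 2); default 8.
#' @param seed Integer seed for the fold shuffle.
#' @param regularization Soft-margin cost passed to [train_linear_svm()].
#' @return A `pcg_eval`: `confusion` (rows actual, columns predicted, order
#'   normal then pathological), `accuracy_percent`, `per_class_percent`,
#'   `roc_points`, `auc`, `fold_assignments`, `decision_values`,
#'   `predicted`.
#' @export
kfold_cross_validate <- function(x, y, k = 8, seed = 1L, regularization = 1) {
  x <- check_xy(x, y)
  check_scalar(k, "k", positive = TRUE, integerish = TRUE)
  if (k < 2) stop_param("`k` must be >= 2")
  folds <- stratified_folds(y, k, seed)

  dv <- numeric(length(y))
  pred <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- folds == f
    model <- train_linear_svm(x[!test, , drop = FALSE], y[!test],
                              regularization = regularization)
    p <- predict(model, x[test, , drop = FALSE])
    dv[test] <- p$decision_values
    pred[test] <- p$labels
  }

  confusion <- matrix(c(sum(y == 1 & pred == 1), sum(y == 1 & pred == -1),
                        sum(y == -1 & pred == 1), sum(y == -1 & pred == -1)),
                      2, 2, byrow = TRUE,
                      dimnames = list(actual = c("normal", "pathological"),
                                      predicted = c("normal", "pathological")))
  cmx <- confusion_metrics(confusion)
  roc <- roc_auc(dv, y)
  structure(list(confusion = confusion,
                 accuracy_percent = cmx$accuracy_percent,
                 per_class_percent = cmx$per_class_percent,
                 roc_points = roc$roc_points, auc = roc$auc,
                 fold_assignments = folds, decision_values = dv,
                 predicted = pred),
            class = "pcg_eval")
}

#' @export
print.pcg_eval <- function(x, ...) {
  cat("Cross-validated evaluation\n")
  print(x$confusion)
  cat(sprintf("accuracy: %.1f%%  (normal %.1f%%, pathological %.1f%%)\n",
              x$accuracy_percent, x$per_class_percent["normal"],
              x$per_class_percent["pathological"]))
  cat(sprintf("AUC: %.3f\n", x$auc))
  invisible(x)
}
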