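test_that("two-point problem recovers the analytic max-margin solution", {
  x <- matrix(c(-1, 1), 2, 1)
  y <- c(-1, 1)
  m <- train_linear_svm(x, y, regularization = 100, standardize = FALSE)
  expect_equal(unname(m$w), 1, tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
  expect_equal(m$margin, 2, tolerance = 1e-6)
  p <- predict(m, x)
  expect_equal(p$decision_values, c(-1, 1), tolerance = 1e-6)
})

test_that("separable clusters are classified perfectly", {
  set.seed(17)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  y <- c(rep(-1, 20), rep(1, 20))
  m <- train_linear_svm(x, y)
  expect_identical(predict(m, x)$labels, y)
})

test_that("degenerate training inputs are rejected", {
  expect_error(train_linear_svm(matrix(1:4, 2), c(1, 1)), "both classes")
  expect_error(train_linear_svm(matrix(c(1, NA, 3, 4), 2), c(-1, 1)),
               "non-finite")
  m <- train_linear_svm(matrix(c(-1, 1), 2, 1), c(-1, 1))
  expect_error(predict(m, matrix(1, 1, 3)), "dimensionality")
})

test_that("a point on the boundary is labeled +1 (healthy)", {
  m <- train_linear_svm(matrix(c(-1, 1), 2, 1), c(-1, 1),
                        regularization = 100, standardize = FALSE)
  p <- predict(m, matrix(0, 1, 1))
  expect_equal(p$decision_values, 0, tolerance = 1e-6)
  expect_identical(p$labels, 1)
})

test_that("confusion metrics reproduce printed percentages", {
  cm <- matrix(c(56, 2, 7, 51), 2, 2, byrow = TRUE)
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy_percent, 100 * 107 / 116)
  expect_equal(unname(m$per_class_percent), c(100 * 56 / 58, 100 * 51 / 58))

  perfect <- confusion_metrics(matrix(c(58, 0, 0, 58), 2, 2))
  expect_equal(perfect$accuracy_percent, 100)
  expect_equal(unname(perfect$per_class_percent), c(100, 100))
  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
})

test_that("ROC/AUC follows the concordance definition", {
  sep <- roc_auc(c(3, 2, -2, -3), c(1, 1, -1, -1))
  expect_equal(sep$auc, 1)
  flat <- roc_auc(rep(0.5, 6), c(1, -1, 1, -1, 1, -1))
  expect_equal(flat$auc, 0.5)
  ex <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1))
  expect_equal(ex$auc, 0.75)

  # curve anatomy: (0,0) to (1,1), both coordinates non-decreasing
  expect_equal(unlist(ex$roc_points[1, c("fpr", "tpr")]),
               c(fpr = 0, tpr = 0))
  expect_equal(unlist(ex$roc_points[nrow(ex$roc_points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(ex$roc_points$fpr) >= 0))
  expect_true(all(diff(ex$roc_points$tpr) >= 0))
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both")
})

test_that("threshold-sweep AUC equals brute-force concordance with ties", {
  set.seed(23)
  for (trial in 1:40) {
    n <- sample(4:12, 1)
    labels <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    values <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(values, labels)$auc,
                 auc_concordance(values, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(29)
  values <- rnorm(40)
  labels <- ifelse(values + rnorm(40) > 0, 1, -1)
  if (length(unique(labels)) == 2) {
    ours <- roc_auc(values, labels)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, values, quiet = TRUE)))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("stratified folds have the expected sizes and determinism", {
  y <- c(rep(1, 58), rep(-1, 58))
  x <- matrix(rnorm(116 * 3), 116, 3)
  r1 <- kfold_cross_validate(x, y, k = 8, seed = 5)
  sizes <- sort(as.vector(table(r1$fold_assignments)))
  expect_identical(sizes, c(rep(14L, 4), rep(15L, 4)))
  # stratification: each fold holds 7 or 8 per class
  per_class <- table(r1$fold_assignments, y)
  expect_true(all(per_class >= 7 & per_class <= 8))

  r2 <- kfold_cross_validate(x, y, k = 8, seed = 5)
  expect_identical(r1$fold_assignments, r2$fold_assignments)
  expect_identical(r1$confusion, r2$confusion)
  expect_error(kfold_cross_validate(x[1:10, ], y[c(1:5, 59:63)], k = 8),
               "at least k")
})

test_that("separable data cross-validates perfectly", {
  set.seed(19)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 8), 30, 2))
  y <- c(rep(-1, 30), rep(1, 30))
  r <- kfold_cross_validate(x, y, k = 5, seed = 2)
  expect_equal(r$accuracy_percent, 100)
  expect_equal(r$auc, 1)
  expect_equal(sum(r$confusion), 60)
})

test_that("fold standardization never sees the test fold", {
  set.seed(37)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c(1, -1), 20)
  r1 <- kfold_cross_validate(x, y, k = 4, seed = 9)
  target_fold <- r1$fold_assignments[1]
  x2 <- x
  x2[1, ] <- x2[1, ] + 1000  # perturb one test-fold row only
  r2 <- kfold_cross_validate(x2, y, k = 4, seed = 9)
  same_fold <- which(r1$fold_assignments == target_fold)
  others <- setdiff(same_fold, 1)
  # the model for that fold was trained without row 1, so its predictions
  # for the rest of the fold are unchanged
  expect_equal(r1$decision_values[others], r2$decision_values[others],
               tolerance = 1e-10)
})
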