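test_that("roc_auc handles perfect ranking, ties, and matches the pairwise oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("case", "case", "control", "control"))$auc, 1.0)
  expect_equal(roc_auc(c(0.5, 0.5), c("case", "control"))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("case", 3)), "both classes")
  set.seed(21)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    labels <- sample(rep(c("case", "control"), length.out = n))
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  labels <- sample(rep(c("case", "control"), 15))
  scores <- rnorm(30)
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, base)
  expect_equal(roc_auc(qlogis(plogis(scores)) * 3 + 2, labels)$auc, base)
})

test_that("ROC points run from (0,0) to (1,1) monotonically", {
  set.seed(5)
  roc <- roc_auc(round(rnorm(40), 1),
                 sample(rep(c("case", "control"), 20)))$roc_points
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("every registry classifier separates an easy problem and is seed-reproducible", {
  train <- random_fm(60, 3, seed = 1, informative = 2, effect = 4)
  test <- random_fm(40, 3, seed = 2, informative = 2, effect = 4)
  for (nm in classifier_registry()) {
    e1 <- fit_evaluate(train, test, clf_spec(nm, seed = 99))
    e2 <- fit_evaluate(train, test, clf_spec(nm, seed = 99))
    expect_identical(e1$predictions, e2$predictions)
    expect_gte(e1$auc, 0.95)
    # confusion-matrix identity ties the four metrics together
    n_pos <- sum(feature_labels(test) == "case")
    n_neg <- sum(feature_labels(test) == "control")
    expect_equal(e1$accuracy,
                 (e1$sensitivity * n_pos + e1$specificity * n_neg) /
                   (n_pos + n_neg))
  }
})

test_that("logistic regression achieves perfect metrics on separable data", {
  train <- random_fm(50, 2, seed = 3, informative = 2, effect = 8)
  test <- random_fm(30, 2, seed = 4, informative = 2, effect = 8)
  ev <- fit_evaluate(train, test, clf_spec("logistic"))
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$accuracy, 1.0)
})

test_that("label-independent features give chance-level AUC", {
  aucs <- vapply(1:10, function(s) {
    train <- random_fm(200, 4, seed = 100 + s)
    test <- random_fm(100, 4, seed = 200 + s)
    fit_evaluate(train, test, clf_spec("logistic", seed = s))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("a constant feature matrix yields AUC 0.5 and a two-point ROC", {
  vals <- matrix(1, 20, 2, dimnames = list(paste0("s", 1:20), c("f1", "f2")))
  fm <- feature_matrix(vals, rep(c("case", "control"), 10))
  ev <- fit_evaluate(fm, fm, clf_spec("logistic"))
  expect_equal(ev$auc, 0.5)
  expect_equal(nrow(ev$roc_points), 2)
})

test_that("errors: single-class training labels and feature mismatch", {
  fm <- random_fm(20, 2, seed = 1)
  one_class <- feature_matrix(unclass(fm), rep("case", 20))
  expect_error(fit_evaluate(one_class, fm, clf_spec("logistic")),
               "single class")
  other <- random_fm(20, 3, seed = 2)
  expect_error(fit_evaluate(fm, other, clf_spec("logistic")), "differ")
})

test_that("decision boundary grids re-predict the model pointwise", {
  train <- random_fm(60, 2, seed = 6, informative = 1, effect = 5)
  model <- fit_classifier(clf_spec("logistic"), train)
  grid <- decision_boundary_grid(model, list(x = c(-3, 6), y = c(-3, 3)),
                                 resolution = 15)
  pts <- as.matrix(expand.grid(grid$x, grid$y))
  colnames(pts) <- model$features
  expect_equal(as.vector(grid$labels),
               as.integer(predict_scores(model, pts) >= 0.5))
  # linear model: each grid row (fixed y) splits into at most one 0-1 switch
  runs <- apply(grid$labels, 2, function(col) sum(diff(col) != 0))
  expect_true(all(runs <= 1))
  wide <- fit_classifier(clf_spec("logistic"), random_fm(30, 3, seed = 7))
  expect_error(decision_boundary_grid(wide, list(x = 0:1, y = 0:1)),
               "exactly 2")
})
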