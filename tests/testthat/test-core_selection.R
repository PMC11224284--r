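test_that("lasso recovers planted informative presence features", {
  hits <- vapply(1:5, function(s) {
    fm <- planted_presence_fm(seed = s)
    sel <- lasso_select(fm, seed = s)
    all(paste0("inf", 1:3) %in% sel$selected_keys)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("lasso limits: no regularization keeps everything, too much errors", {
  fm <- random_fm(50, 5, seed = 8, informative = 2)
  sel <- lasso_select(fm, lambda = 1e-8)
  expect_setequal(sel$selected_keys, colnames(fm))
  expect_error(lasso_select(fm, lambda = 10), "weaken")
})

test_that("lasso retains the signal of a duplicated informative column", {
  # the L1 solution is not unique under exact collinearity: coordinate
  # descent may split the weight across the copies or park it on one of
  # them, but the duplicated signal itself is never discarded
  for (s in 1:5) {
    fm <- planted_presence_fm(n_inform = 1, n_noise = 5, seed = 40 + s)
    x <- cbind(unclass(fm), dup1 = unclass(fm)[, "inf1"])
    sel <- lasso_select(feature_matrix(x, feature_labels(fm)),
                        lambda = 0.05, seed = s)
    expect_true(any(c("inf1", "dup1") %in% sel$selected_keys))
  }
})

test_that("rfecv finds a forced single-feature optimum", {
  # the informative feature is a perfect label copy: CV AUC is 1 wherever it
  # is retained, so the smallest-dimension tie rule must land on it alone
  fm <- planted_presence_fm(n = 120, n_inform = 1, n_noise = 6,
                            p_case = 1, p_ctrl = 0, seed = 10)
  sel <- rfecv_select(fm, clf_spec("logistic", seed = 1), scoring = "auc",
                      seed = 1)
  expect_equal(length(sel$selected_keys), 1)
  expect_equal(sel$selected_keys, "inf1")
})

test_that("rfecv with adaboost recovers planted features at small dimension", {
  ok <- vapply(1:5, function(s) {
    fm <- planted_presence_fm(seed = 20 + s)
    sel <- rfecv_select(fm, clf_spec("adaboost", seed = s), seed = s)
    length(sel$selected_keys) <= 8 &&
      all(paste0("inf", 1:3) %in% sel$selected_keys)
  }, logical(1))
  expect_gte(sum(ok), 4)
})

test_that("rfecv's dimension follows the one-SE parsimony rule on its own trace", {
  for (s in 1:3) {
    fm <- planted_presence_fm(n = 80, n_inform = 2, n_noise = 6, seed = 30 + s)
    sel <- rfecv_select(fm, clf_spec("logistic", seed = s), seed = s)
    scores <- sel$cv_scores
    best <- min(which(scores >= max(scores) - sel$trace$se - 1e-12))
    expect_equal(length(sel$selected_keys), unname(best))
    expect_equal(sel$trace$best_dim, unname(best))
  }
})

test_that("rfecv refuses estimators without a ranking signal", {
  fm <- planted_presence_fm(n = 40, seed = 1)
  expect_error(rfecv_select(fm, clf_spec("knn")), "ranking signal")
})

test_that("backward exclusion drops redundant copies without losing CV AUC", {
  fm0 <- planted_presence_fm(n = 150, n_inform = 2, n_noise = 1,
                             p_case = 0.9, p_ctrl = 0.05, seed = 44)
  x <- unclass(fm0)
  x <- cbind(x, dup1 = x[, "inf1"], dup2 = x[, "inf2"])
  fm <- feature_matrix(x, feature_labels(fm0))
  sel <- backward_exclusion(fm, start_keys = colnames(fm),
                            spec = clf_spec("logistic", seed = 1),
                            tolerance = 0, seed = 1)
  expect_lte(length(sel$selected_keys), 3)
  first <- sel$trace$cv_auc[1]
  expect_gte(min(sel$trace$cv_auc, na.rm = TRUE), first - 1e-12)
})

test_that("backward exclusion with infinite tolerance runs down to one survivor", {
  fm <- planted_presence_fm(n = 60, n_inform = 2, n_noise = 3, seed = 2)
  sel <- backward_exclusion(fm, start_keys = colnames(fm),
                            spec = clf_spec("decision_tree", seed = 1),
                            tolerance = Inf, seed = 1)
  expect_length(sel$selected_keys, 1)
})

test_that("backward exclusion keeps a jointly necessary pair intact", {
  set.seed(77)
  n <- 80
  f1 <- rbinom(n, 1, 0.5); f2 <- rbinom(n, 1, 0.5)
  labels <- ifelse(xor(f1, f2), "case", "control")
  x <- cbind(f1 = f1, f2 = f2)
  rownames(x) <- paste0("s", 1:n)
  fm <- feature_matrix(x, labels)
  sel <- backward_exclusion(fm, start_keys = c("f1", "f2"),
                            spec = clf_spec("random_forest", seed = 3),
                            tolerance = 0, seed = 3)
  expect_setequal(sel$selected_keys, c("f1", "f2"))
})

test_that("the surviving set is a subset chain within tolerance of the running best", {
  fm <- planted_presence_fm(n = 100, n_inform = 2, n_noise = 5, seed = 55)
  tol <- 0.02
  sel <- backward_exclusion(fm, start_keys = colnames(fm),
                            spec = clf_spec("logistic", seed = 2),
                            tolerance = tol, seed = 2)
  expect_true(all(sel$selected_keys %in% colnames(fm)))
  running_best <- sel$trace$cv_auc[1]
  for (i in seq_len(nrow(sel$trace))[-1]) {
    expect_gte(sel$trace$cv_auc[i], running_best - tol - 1e-12)
    running_best <- max(running_best, sel$trace$cv_auc[i])
  }
})

test_that("the estimator-by-classifier grid has the right shape and is deterministic", {
  tr <- planted_presence_fm(n = 120, seed = 60)
  te <- planted_presence_fm(n = 80, seed = 61)
  g1 <- selection_grid(tr, te, c("adaboost", "logistic"),
                       c("svm_linear", "random_forest"), seed = 4)
  g2 <- selection_grid(tr, te, c("adaboost", "logistic"),
                       c("svm_linear", "random_forest"), seed = 4)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 4)
  expect_true(all(g1$auc >= 0 & g1$auc <= 1))
  expect_gte(max(g1$auc), 0.9)
})
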