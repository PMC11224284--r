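test_that("tree importances normalise to one and pick out a label-copy feature", {
  for (method in c("rf", "gbdt", "xgboost_like")) {
    wins <- vapply(1:10, function(s) {
      set.seed(s)
      labels <- rep(c("case", "control"), each = 100)
      x <- cbind(copy = as.numeric(labels == "case") , matrix(rnorm(600), 200, 3))
      colnames(x) <- c("copy", paste0("noise", 1:3))
      rownames(x) <- paste0("s", 1:200)
      imp <- model_importance(feature_matrix(x, labels), method, seed = s)
      expect_equal(sum(imp), 1, tolerance = 1e-9)
      names(which.max(imp)) == "copy"
    }, logical(1))
    expect_gte(sum(wins), 9)
  }
})

test_that("exchangeable noise features receive near-uniform importance", {
  imps <- t(vapply(1:30, function(s) {
    fm <- random_fm(100, 4, seed = 300 + s)
    model_importance(fm, "rf", seed = s)
  }, numeric(4)))
  m <- colMeans(imps)
  se <- apply(imps, 2, sd) / sqrt(nrow(imps))
  expect_true(all(abs(m - 0.25) <= 3 * se + 1e-8))
})

test_that("a single-feature matrix has importance exactly one", {
  fm <- random_fm(30, 1, seed = 1)
  expect_equal(model_importance(fm, "rf"), c(f1 = 1))
})

test_that("permutation importance matches analytic expectations", {
  labels <- rep(c("case", "control"), each = 50)
  x <- cbind(copy = as.numeric(labels == "case"),
             flat = rep(1, 100))
  rownames(x) <- paste0("s", 1:100)
  fm <- feature_matrix(x, labels)
  model <- fit_classifier(clf_spec("decision_tree", seed = 1), fm)
  drops <- permutation_importance(model, fm, n_repeats = 50, seed = 2)
  # permuting a perfect predictor at class balance halves accuracy
  expect_equal(unname(drops["copy"]), 0.5, tolerance = 0.05)
  # permuting a constant column changes nothing, exactly
  expect_identical(unname(drops["flat"]), 0)
  expect_error(permutation_importance(model, fm, n_repeats = 0), "n_repeats")
})

test_that("repeating permutations shrinks the variance, not the expectation", {
  fm <- planted_presence_fm(n = 120, n_inform = 1, n_noise = 3, seed = 5)
  model <- fit_classifier(clf_spec("random_forest", seed = 5), fm)
  one <- vapply(1:15, function(s)
    permutation_importance(model, fm, n_repeats = 1, seed = s)["inf1"],
    numeric(1))
  many <- vapply(1:15, function(s)
    permutation_importance(model, fm, n_repeats = 25, seed = s)["inf1"],
    numeric(1))
  expect_equal(mean(one), mean(many), tolerance = 0.1)
  expect_lt(var(many), var(one))
})

test_that("rank aggregation sums importances and dense mean ranks", {
  v <- c(a = 0.5, b = 0.3, c = 0.2)
  agg <- aggregate_importance(list(m1 = v, m2 = v))
  expect_equal(agg$sum_of_importance, 2 * v)
  expect_equal(agg$sum_of_ranks, c(a = 2, b = 4, c = 6))
  expect_identical(agg$ordering, c("a", "b", "c"))
  # reversed rankings over 4 features: all rank-sums equal
  up <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  down <- rev(up); names(down) <- names(up)
  agg2 <- aggregate_importance(list(up, down))
  expect_true(all(agg2$sum_of_ranks == 5))
  # supplying methods in another order changes nothing
  agg3 <- aggregate_importance(list(down, up))
  expect_equal(agg3$sum_of_ranks, agg2$sum_of_ranks)
  expect_error(aggregate_importance(list(v, c(x = 1, y = 0, z = 0))),
               "aligned")
})

test_that("the four-method index panel runs end to end on diversity features", {
  coh <- generate_cohort(small_config(seed = 3, incidence_case = 0.9,
                                      incidence_ctrl = 0.05))
  fm <- diversity_feature_table(coh$train)
  panel <- importance_panel(fm, n_repeats = 5, seed = 1)
  expect_named(panel$per_method, c("rf", "gbdt", "xgboost_like", "permutation"))
  for (m in c("rf", "gbdt", "xgboost_like"))
    expect_equal(sum(panel$per_method[[m]]), 1, tolerance = 1e-9)
  expect_length(panel$aggregate$ordering, 6)
})
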