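test_that("presence counts tally membership by phenotype", {
  ph <- rep(c("case", "control"), each = 5)
  all_cases <- membership_cohort(c(rep(TRUE, 5), rep(FALSE, 5)), ph)
  expect_equal(presence_counts(all_cases, tracked_key),
               c(a = 5, b = 0, c = 0, d = 5))
  nobody <- membership_cohort(rep(FALSE, 10), ph)
  expect_equal(presence_counts(nobody, tracked_key),
               c(a = 0, b = 5, c = 0, d = 5))
  mixed <- membership_cohort(c(TRUE, FALSE, TRUE, TRUE, FALSE,
                               TRUE, FALSE, FALSE, FALSE, TRUE), ph)
  expect_equal(presence_counts(mixed, tracked_key),
               c(a = 3, b = 2, c = 2, d = 3))
})

test_that("fisher P-values match hand-enumerated hypergeometric values", {
  expect_equal(fisher_exact_p(5, 0, 0, 5), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_p(2, 3, 2, 3), 1.0)
  expect_equal(fisher_exact_p(5, 0, 0, 5, alternative = "case_enriched"),
               1 / choose(10, 5), tolerance = 1e-12)
  expect_error(fisher_exact_p(-1, 2, 3, 4), "negative")
})

test_that("fisher agrees with stats::fisher.test across a margin sweep", {
  for (m in 1:8) for (n in 1:8) for (a in 0:m) for (cc in 0:n) {
    ours <- fisher_exact_p(a, m - a, cc, n - cc)
    ref <- stats::fisher.test(matrix(c(a, m - a, cc, n - cc), 2,
                                     byrow = TRUE))$p.value
    expect_equal(ours, min(1, ref), tolerance = 1e-10)
  }
})

test_that("two-sided fisher is symmetric under case/control exchange", {
  set.seed(3)
  for (i in 1:50) {
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    cc <- sample(0:10, 1); d <- sample(0:10, 1)
    if (a + b + cc + d == 0) next
    expect_equal(fisher_exact_p(a, b, cc, d), fisher_exact_p(cc, d, a, b),
                 tolerance = 1e-12)
  }
})

test_that("screen finds a planted clone and ignores balanced ones", {
  ph <- rep(c("case", "control"), each = 10)
  members <- c(rep(TRUE, 9), FALSE, rep(FALSE, 10))  # 9/10 cases, 0 controls
  cohort <- membership_cohort(members, ph)
  hits <- screen(cohort, cutoff = 0.01)
  expect_true(tracked_key %in% hits$key)
  # shared background clones are present everywhere: never significant
  expect_equal(nrow(hits), 1)
  expect_equal(hits$a, 9)
  expect_equal(hits$c, 0)
})

test_that("screen at cutoff 1 returns every observed key, sorted deterministically", {
  ph <- rep(c("case", "control"), each = 4)
  cohort <- membership_cohort(c(TRUE, TRUE, FALSE, FALSE,
                                FALSE, TRUE, FALSE, FALSE), ph)
  all_keys <- sort(unique(unlist(lapply(cohort, repertoire_keys))))
  out <- screen(cohort, cutoff = 1.0)
  expect_setequal(out$key, all_keys)
  expect_true(!is.unsorted(out$p_value))
  ties <- split(out$key, out$p_value)
  for (grp in ties) expect_identical(grp, sort(grp))
})

test_that("a cutoff below the attainable minimum yields an empty screen", {
  ph <- rep(c("case", "control"), each = 3)
  cohort <- membership_cohort(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), ph)
  # most extreme table with margins 3/3 has p = 2/C(6,3) = 0.1
  out <- screen(cohort, cutoff = 0.05)
  expect_equal(nrow(out), 0)
})

test_that("threshold traversal produces nested key sets in one pass", {
  coh <- generate_cohort(small_config(seed = 5))
  sets <- threshold_traverse(coh$train, c(0.5, 0.1, 1e-2, 1e-3))
  expect_length(sets, 4)
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  one <- threshold_traverse(coh$train, 1.0)
  expect_length(one, 1)
  expect_setequal(one[[1]],
                  unique(unlist(lapply(coh$train, repertoire_keys))))
})

test_that("null cohorts keep the sub-0.1 discovery fraction near nominal", {
  fracs <- vapply(1:5, function(s) {
    coh <- generate_cohort(small_config(seed = s, incidence_case = 0.3,
                                        incidence_ctrl = 0.3))
    all_p <- screen(coh$train, cutoff = 1.0)
    mean(all_p$p_value < 0.1)
  }, numeric(1))
  n_keys <- 1000  # conservative lower bound on keys per cohort
  expect_lte(mean(fracs), 0.1 + 3 * sqrt(0.1 * 0.9 / n_keys))
})
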