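#' Tree-ensemble feature importance
#'
#' Fits one of the tree ensembles (random forest, gradient-boosted trees with
#' exact or histogram growth) on a labelled feature matrix and returns its
#' intrinsic importance vector, normalised to sum to one.
#'
#' @param train a `tcr_features` matrix with both classes.
#' @param method `"rf"`, `"gbdt"` or `"xgboost_like"`.
#' @param seed fitting seed.
#' @return non-negative named vector aligned with the feature names, summing
#'   to 1.
#' @export
model_importance <- function(train, method = c("rf", "gbdt", "xgboost_like"),
                             seed = 1L) {
  method <- match.arg(method)
  if (ncol(train) == 1)
    return(stats::setNames(1, colnames(train)))
  name <- c(rf = "random_forest", gbdt = "gbdt",
            xgboost_like = "xgboost_like")[method]
  model <- fit_classifier(clf_spec(name, seed = seed), train)
  imp <- model_feature_importance(model)
  if (sum(imp) == 0) imp[] <- 1   # no splits made: uninformative, uniform
  imp / sum(imp)
}

#' Permutation importance (accuracy drop)
#'
#' For each feature, shuffles its column and measures the mean decrease in
#' hard-label accuracy of an already-fitted model over `n_repeats` shuffles.
#' Drops can be negative when a permutation accidentally helps.
#'
#' @param model a fitted `tcr_model`.
#' @param fm `tcr_features` to evaluate on (typically the training matrix).
#' @param n_repeats shuffles per feature (>= 1).
#' @param seed RNG seed for the shuffles.
#' @return named vector of mean accuracy drops per feature.
#' @export
permutation_importance <- function(model, fm, n_repeats = 10, seed = 1L) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  x <- unclass(fm); attr(x, "labels") <- NULL
  labels <- feature_labels(fm)
  is_case <- labels == "case"
  threshold <- if (model$type == "prob") 0.5 else 0
  acc <- function(xm) {
    mean((predict_scores(model, xm) >= threshold) == is_case)
  }
  baseline <- acc(x)
  set.seed(seed)
  drops <- vapply(seq_len(ncol(x)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- x[sample.int(nrow(x)), j]
      baseline - acc(xp)
    }, numeric(1)))
  }, numeric(1))
  stats::setNames(drops, colnames(x))
}

#' Aggregate importance vectors across ranking methods
#'
#' Combines per-method importance vectors two ways: the elementwise sum of
#' importances, and the sum of per-method ranks (rank 1 = most important;
#' ties share the mean rank). Lower rank-sum means more consistently
#' important.
#'
#' @param vectors named list of importance vectors over the same features.
#' @return list with `sum_of_importance`, `sum_of_ranks` (both named vectors)
#'   and `ordering` (feature names by increasing rank-sum, importance-sum as
#'   tie-break).
#' @export
aggregate_importance <- function(vectors) {
  stopifnot(length(vectors) >= 1)
  feats <- names(vectors[[1]])
  for (v in vectors) {
    if (!identical(sort(names(v)), sort(feats)))
      stop("importance vectors are not aligned on one feature list",
           call. = FALSE)
  }
  mat <- do.call(rbind, lapply(vectors, function(v) v[feats]))
  sum_imp <- colSums(mat)
  ranks <- t(apply(mat, 1, function(v) rank(-v, ties.method = "average")))
  if (length(feats) == 1) ranks <- matrix(1, nrow = length(vectors))
  sum_rank <- stats::setNames(colSums(ranks), feats)
  ordering <- feats[order(sum_rank, -sum_imp, feats)]
  list(sum_of_importance = sum_imp, sum_of_ranks = sum_rank,
       ordering = ordering)
}

#' The four-method importance panel for the diversity indices
#'
#' Convenience preset reproducing the index-ranking experiment: random
#' forest, two gradient-boosting variants, and permutation importance under a
#' random-forest model, aggregated by importance-sum and rank-sum.
#'
#' @param train a `tcr_features` matrix (typically six diversity indices).
#' @param n_repeats permutation shuffles.
#' @param seed seed shared by all four methods.
#' @return list with `per_method` (named list of vectors) and `aggregate`
#'   (result of [aggregate_importance()]).
#' @export
importance_panel <- function(train, n_repeats = 20, seed = 1L) {
  per <- list(
    rf = model_importance(train, "rf", seed = seed),
    gbdt = model_importance(train, "gbdt", seed = seed),
    xgboost_like = model_importance(train, "xgboost_like", seed = seed),
    permutation = permutation_importance(
      fit_classifier(clf_spec("random_forest", seed = seed), train),
      train, n_repeats = n_repeats, seed = seed)
  )
  list(per_method = per, aggregate = aggregate_importance(per))
}
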