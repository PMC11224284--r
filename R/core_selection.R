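# Core-marker reduction: Lasso, RFECV over importance-bearing estimators, and
# greedy backward (one-by-one) exclusion, all scored by stratified
# cross-validation on the training split only.

new_selection_result <- function(method, selected_keys, cv_scores = NULL,
                                 trace = NULL, final_eval = NULL) {
  stopifnot(length(selected_keys) >= 1)
  structure(list(method = method, selected_keys = selected_keys,
                 cv_scores = cv_scores, trace = trace,
                 final_eval = final_eval),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d features [%s]\n", x$method,
              length(x$selected_keys),
              paste(utils::head(x$selected_keys, 5), collapse = ", ")))
  invisible(x)
}

# Repeated stratified fold splits, flattened: a list of held-out index
# vectors spanning `repeats` independent k-fold partitions. Scores are
# per-fold (scale-safe for margin classifiers, whose decision values are not
# comparable across refits) and averaged over all folds of all repetitions,
# which damps the split-to-split noise that otherwise dominates
# small-cohort CV curves.
make_repeated_folds <- function(y, k, repeats, seed) {
  unlist(lapply(seq_len(repeats),
                function(r) make_folds(y, k, seed = seed + r - 1)),
         recursive = FALSE)
}

fold_metric <- function(scores, labels, type, scoring) {
  if (scoring == "auc") {
    roc_auc(scores, labels)$auc
  } else {
    thr <- if (type == "prob") 0.5 else 0
    mean((scores >= thr) == (labels == "case"))
  }
}

# mean per-fold score of `spec` on a feature subset of `fm`
cv_score <- function(fm, spec, folds, scoring = c("auc", "accuracy")) {
  scoring <- match.arg(scoring)
  labels <- feature_labels(fm)
  mean(vapply(folds, function(f) {
    tr <- feature_matrix(unclass(fm)[-f, , drop = FALSE], labels[-f])
    model <- fit_classifier(spec, tr)
    sc <- predict_scores(model, unclass(fm)[f, , drop = FALSE])
    fold_metric(sc, labels[f], model$type, scoring)
  }, numeric(1)))
}

#' Lasso feature selection on a presence matrix
#'
#' L1-penalised logistic regression; the selected features are those with a
#' non-zero coefficient at the chosen penalty. By default the penalty is
#' picked by cross-validated deviance (`lambda.min`); pass `lambda` to fix
#' it. The full coefficient path is recorded.
#'
#' @param train a `tcr_features` matrix with binary labels and >= 2 features.
#' @param lambda penalty strength, or `NULL` for CV choice.
#' @param test optional `tcr_features`; when given, a logistic model on the
#'   selected features is evaluated on it (`final_eval`).
#' @param seed RNG seed (CV folds).
#' @return a `selection_result`; `trace` holds the path (`lambda`,
#'   `n_nonzero`).
#' @export
lasso_select <- function(train, lambda = NULL, test = NULL, seed = 1L) {
  if (ncol(train) < 2) stop("need >= 2 features", call. = FALSE)
  y <- labels_to_y(feature_labels(train))
  x <- unclass(train); attr(x, "labels") <- NULL
  set.seed(seed)
  if (is.null(lambda)) {
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                               nfolds = 5)
    lambda <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1)
  }
  co <- as.matrix(stats::coef(fit, s = lambda))[-1, 1]
  selected <- names(co)[co != 0]
  if (!length(selected))
    stop("lasso selected no features; weaken the regularization (smaller ",
         "lambda)", call. = FALSE)
  path <- data.frame(lambda = fit$lambda,
                     n_nonzero = fit$df)
  final <- if (!is.null(test)) {
    fit_evaluate(fm_select(train, selected), fm_select(test, selected),
                 clf_spec("logistic", seed = seed))
  }
  res <- new_selection_result("lasso", selected, trace = path,
                              final_eval = final)
  res$lambda <- lambda
  res
}

# one pass of recursive feature elimination on a fixed training matrix;
# returns feature sets from full down to 1 and, when a held-out fold is
# given, the raw held-out scores at every size (pooled later across folds)
rfe_path <- function(fm, estimator, eval_fm = NULL) {
  feats <- colnames(fm)
  sizes <- seq(length(feats), 1)
  kept <- vector("list", length(sizes))
  scores <- vector("list", length(sizes))
  current <- feats
  type <- "prob"
  for (i in seq_along(sizes)) {
    sub <- fm_select(fm, current)
    model <- fit_classifier(estimator, sub)
    type <- model$type
    if (!is.null(eval_fm)) {
      scores[[i]] <- predict_scores(model, fm_select(eval_fm, current))
    }
    kept[[i]] <- current
    if (length(current) > 1) {
      imp <- model_feature_importance(model)
      # drop the least important; break importance ties lexicographically
      drop <- current[order(imp[current], current)][1]
      current <- setdiff(current, drop)
    }
  }
  list(sizes = sizes, kept = kept, scores = scores, type = type)
}

#' Recursive feature elimination with cross-validation
#'
#' Within each stratified CV fold of each repetition, features are
#' eliminated one at a time (always the estimator's least-important
#' remaining feature) and the fold's held-out score is recorded at every
#' dimension; the CV curve is the mean over all folds of all repetitions.
#' The returned dimension is the smallest one whose mean CV score lies
#' within one standard error of the maximum — the usual parsimony rule for
#' model selection under CV noise; the final feature set is obtained by
#' eliminating down to that dimension on the full training split.
#'
#' @param train a `tcr_features` matrix.
#' @param estimator a [clf_spec()] whose model exposes a ranking signal
#'   (coefficients or tree importance).
#' @param cv_folds number of stratified folds (>= 2).
#' @param scoring `"auc"` or `"accuracy"`.
#' @param test optional held-out `tcr_features` for `final_eval` (scored with
#'   the estimator itself).
#' @param seed fold-shuffling seed.
#' @return a `selection_result` with `cv_scores` = mean CV score per
#'   dimension (names = dimension).
#' @export
rfecv_select <- function(train, estimator, cv_folds = 5, cv_repeats = 3,
                         scoring = c("auc", "accuracy"), test = NULL,
                         seed = 1L) {
  scoring <- match.arg(scoring)
  stopifnot(cv_folds >= 2, cv_repeats >= 1)
  # verify the estimator carries a ranking signal before doing any work
  if (is.null(.registry[[estimator$name]]$importance))
    stop("estimator '", estimator$name, "' has no feature-ranking signal",
         call. = FALSE)
  y <- labels_to_y(feature_labels(train))
  folds <- make_repeated_folds(y, k = min(cv_folds, min(table(y))),
                               repeats = cv_repeats, seed = seed)
  p <- ncol(train)
  labels <- feature_labels(train)
  fold_scores <- matrix(NA_real_, nrow = p, ncol = length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    tr <- feature_matrix(unclass(train)[-f, , drop = FALSE], labels[-f])
    te <- feature_matrix(unclass(train)[f, , drop = FALSE], labels[f])
    path <- rfe_path(tr, estimator, eval_fm = te)
    fold_scores[path$sizes, i] <- vapply(seq_along(path$sizes), function(j) {
      fold_metric(path$scores[[j]], labels[f], path$type, scoring)
    }, numeric(1))
  }
  mean_scores <- rowMeans(fold_scores)
  # parsimony ("one standard error") rule: the smallest dimension whose CV
  # score is within one SE of the maximum. A strict arg-max chases CV noise
  # upward in dimension at cohort sizes like these.
  i_max <- which.max(mean_scores)
  se <- stats::sd(fold_scores[i_max, ]) / sqrt(ncol(fold_scores))
  best_dim <- which(mean_scores >= mean_scores[i_max] - se - 1e-12)[1]
  full_path <- rfe_path(train, estimator)
  selected <- full_path$kept[[match(best_dim, full_path$sizes)]]
  final <- if (!is.null(test)) {
    fit_evaluate(fm_select(train, selected), fm_select(test, selected),
                 estimator)
  }
  new_selection_result(
    paste0("rfecv_", estimator$name), selected,
    cv_scores = stats::setNames(mean_scores, seq_len(p)),
    trace = list(fold_scores = fold_scores, best_dim = best_dim, se = se),
    final_eval = final
  )
}

#' Greedy one-by-one backward exclusion
#'
#' Starting from a candidate marker set, repeatedly drops the single feature
#' whose removal maximises (or least harms) the cross-validated AUC of the
#' given classifier on the training split; a removal is accepted while the
#' score stays within `tolerance` of the best score seen so far. With the
#' default `tolerance = 0` only removals that do not hurt CV AUC survive.
#'
#' @param train `tcr_features` training matrix.
#' @param test optional `tcr_features` for final held-out evaluation.
#' @param start_keys ordered candidate feature subset.
#' @param spec classifier used for scoring (a [clf_spec()]).
#' @param tolerance allowed CV-AUC drop from the running best (`Inf` runs the
#'   loop to a single survivor).
#' @param cv_folds stratified folds for the CV score.
#' @param cv_repeats fold-split repetitions averaged into each CV score.
#' @param seed fold-shuffling seed (fold splits are fixed across the whole
#'   loop so scores are comparable).
#' @return a `selection_result`; `trace` is a data frame of accepted removals
#'   (`removed`, `size_after`, `cv_auc`).
#' @export
backward_exclusion <- function(train, test = NULL, start_keys, spec,
                               tolerance = 0, cv_folds = 5, cv_repeats = 3,
                               seed = 1L) {
  if (!length(start_keys)) stop("start_keys is empty", call. = FALSE)
  y <- labels_to_y(feature_labels(train))
  folds <- make_repeated_folds(y, k = min(cv_folds, min(table(y))),
                               repeats = cv_repeats, seed = seed)
  current <- start_keys
  best_seen <- cv_score(fm_select(train, current), spec, folds)
  trace <- data.frame(removed = NA_character_, size_after = length(current),
                      cv_auc = best_seen, stringsAsFactors = FALSE)
  while (length(current) > 1) {
    cand <- sort(current)
    sc <- vapply(cand, function(f) {
      cv_score(fm_select(train, setdiff(current, f)), spec, folds)
    }, numeric(1))
    pick <- cand[which.max(sc)]
    if (best_seen - max(sc) <= tolerance) {
      current <- setdiff(current, pick)
      best_seen <- max(best_seen, max(sc))
      trace <- rbind(trace, data.frame(removed = pick,
                                       size_after = length(current),
                                       cv_auc = max(sc),
                                       stringsAsFactors = FALSE))
    } else break
  }
  final <- if (!is.null(test)) {
    fit_evaluate(fm_select(train, current), fm_select(test, current), spec)
  }
  new_selection_result("backward_exclusion", current, trace = trace,
                       final_eval = final)
}

#' Cross-product grid of RFECV estimators and evaluation classifiers
#'
#' Runs [rfecv_select()] once per estimator, then evaluates every (selected
#' set, classifier) pair on the held-out test split.
#'
#' @param train,test `tcr_features` matrices sharing feature names.
#' @param estimators character vector of registry names with a ranking
#'   signal.
#' @param classifiers character vector of registry names for evaluation.
#' @param cv_folds,seed passed to [rfecv_select()] and the classifier specs.
#' @return data frame with one row per (estimator, classifier): selected
#'   `dimension`, `auc`, `accuracy`, `sensitivity`, `specificity`.
#' @export
selection_grid <- function(train, test, estimators, classifiers,
                           cv_folds = 5, seed = 1L) {
  stopifnot(length(estimators) >= 1, length(classifiers) >= 1)
  rows <- list()
  for (est in estimators) {
    sel <- rfecv_select(train, clf_spec(est, seed = seed),
                        cv_folds = cv_folds, seed = seed)
    for (cls in classifiers) {
      ev <- fit_evaluate(fm_select(train, sel$selected_keys),
                         fm_select(test, sel$selected_keys),
                         clf_spec(cls, seed = seed))
      rows[[length(rows) + 1]] <- data.frame(
        estimator = est, classifier = cls,
        dimension = length(sel$selected_keys),
        auc = ev$auc, accuracy = ev$accuracy,
        sensitivity = ev$sensitivity, specificity = ev$specificity,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
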