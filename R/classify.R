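#' ROC curve and AUC from continuous scores
#'
#' The AUC is the Mann-Whitney statistic U / (n+ * n-) (probability that a
#' random case outranks a random control, ties counted 1/2), computed from
#' midranks. ROC points are swept over thresholds at the distinct score
#' values.
#'
#' @param scores numeric vector of case-scores.
#' @param labels phenotype labels (`"case"`/`"control"`), both present.
#' @return list with `auc` and `roc_points` (data frame `fpr`, `tpr`, from
#'   (0,0) to (1,1), monotone in both coordinates).
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "case"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n_neg, numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  list(auc = auc, roc_points = roc)
}

#' Train one classifier and evaluate it on a held-out split
#'
#' Fits the model on the training matrix only and scores the test split.
#' Hard predictions for accuracy/sensitivity/specificity use the natural
#' threshold of the score type: 0.5 for probabilities, 0 for margins.
#' Sensitivity is case recall (positive class = case), specificity control
#' recall.
#'
#' @param train,test `tcr_features` matrices sharing feature names.
#' @param spec a [clf_spec()].
#' @return object of class `eval_result`: list with `classifier`, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`, `roc_points`, `predictions`
#'   (per-sample scores) and `threshold`.
#' @export
fit_evaluate <- function(train, test, spec) {
  if (!identical(colnames(train), colnames(test)))
    stop("train and test feature names differ", call. = FALSE)
  model <- fit_classifier(spec, train)
  scores <- predict_scores(model, test)
  labels <- feature_labels(test)
  threshold <- if (model$type == "prob") 0.5 else 0
  evaluate_scores(scores, labels, threshold, spec$name)
}

evaluate_scores <- function(scores, labels, threshold, name = NA_character_) {
  ra <- roc_auc(scores, labels)
  pred_case <- scores >= threshold
  is_case <- labels == "case"
  structure(list(
    classifier = name,
    auc = ra$auc,
    accuracy = mean(pred_case == is_case),
    sensitivity = sum(pred_case & is_case) / sum(is_case),
    specificity = sum(!pred_case & !is_case) / sum(!is_case),
    roc_points = ra$roc_points,
    predictions = scores,
    threshold = threshold
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: AUC=%.3f acc=%.3f sens=%.3f spec=%.3f\n",
              x$classifier, x$auc, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Evaluate a bank of classifiers on one feature representation
#'
#' @param train,test `tcr_features` matrices sharing feature names.
#' @param classifiers character vector of registry names (default: the full
#'   registry).
#' @param seed seed applied to every model fit.
#' @return data frame with one row per classifier: `classifier`, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
classify_bank <- function(train, test, classifiers = classifier_registry(),
                          seed = 1L) {
  rows <- lapply(classifiers, function(nm) {
    ev <- fit_evaluate(train, test, clf_spec(nm, seed = seed))
    data.frame(classifier = nm, auc = ev$auc, accuracy = ev$accuracy,
               sensitivity = ev$sensitivity, specificity = ev$specificity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Decision-boundary label grid for a two-feature model
#'
#' Evaluates a fitted two-feature model's hard prediction over a regular grid,
#' for contour-style visualisation of its decision boundary.
#'
#' @param model a `tcr_model` fitted on exactly two features.
#' @param bounds list with `x = c(min, max)`, `y = c(min, max)`.
#' @param resolution grid points per axis.
#' @return list with `x`, `y` (axis coordinates) and `labels`
#'   (resolution x resolution matrix of 0/1 predicted labels; rows follow
#'   `x`, columns `y`).
#' @export
decision_boundary_grid <- function(model, bounds, resolution = 100) {
  if (length(model$features) != 2)
    stop("model must be fitted on exactly 2 features", call. = FALSE)
  gx <- seq(bounds$x[1], bounds$x[2], length.out = resolution)
  gy <- seq(bounds$y[1], bounds$y[2], length.out = resolution)
  pts <- as.matrix(expand.grid(gx, gy))
  colnames(pts) <- model$features
  scores <- predict_scores(model, pts)
  threshold <- if (model$type == "prob") 0.5 else 0
  list(x = gx, y = gy,
       labels = matrix(as.integer(scores >= threshold), nrow = resolution))
}
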