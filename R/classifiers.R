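# Classifier registry. Each entry wraps an established implementation (or a
# small self-contained one where none is installed) behind a uniform
# fit/predict/importance surface. Scores are continuous: class-1 ("case")
# probability for type "prob", a signed margin for type "margin".

#' Classifier specification
#'
#' @param name one of [classifier_registry()].
#' @param hyper named list of hyperparameter overrides for the model's
#'   recorded defaults.
#' @param seed integer seed; every stochastic model is fitted under it, so a
#'   fit is reproducible from (data, spec).
#' @return object of class `clf_spec`.
#' @export
clf_spec <- function(name, hyper = list(), seed = 1L) {
  name <- match.arg(name, classifier_registry())
  structure(list(name = name, hyper = hyper, seed = as.integer(seed)),
            class = "clf_spec")
}

#' Names of the available classifiers
#'
#' The bank covers every algorithm family used in the analysis: classical
#' (logistic, LDA, linear/polynomial SVM, naive Bayes, decision tree, kNN),
#' ensembles (random forest, two gradient-boosting variants, AdaBoost,
#' bagging), a single-hidden-layer neural network, and a cross-validated
#' Platt-calibrated linear SVM.
#'
#' @return character vector of registry names.
#' @export
classifier_registry <- function() names(.registry)

default_hyper <- list(
  logistic = list(),
  lda = list(),
  svm_linear = list(cost = 1),
  svm_poly = list(cost = 1, degree = 3),
  naive_bayes = list(laplace = 0),
  decision_tree = list(),
  knn = list(k = 5),
  random_forest = list(ntree = 500),
  gbdt = list(nrounds = 100, eta = 0.1, max_depth = 3),
  xgboost_like = list(nrounds = 100, eta = 0.1, max_depth = 6, lambda = 1),
  adaboost = list(n_estimators = 50),
  bagging = list(n_estimators = 50),
  mlp = list(size = 8, decay = 0.01, maxit = 500),
  calibrated_cv = list(folds = 5, cost = 1)
)

labels_to_y <- function(labels) {
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case'/'control'", call. = FALSE)
  factor(labels, levels = c("control", "case"))
}

drop_constant <- function(x) {
  keep <- apply(x, 2, function(col) stats::var(col) > 0)
  if (!any(keep)) keep[1] <- TRUE   # keep one column; model degenerates gracefully
  x[, keep, drop = FALSE]
}

# orientation helper: margin models whose sign convention depends on level
# order are flipped so that larger score = more case-like on the train set
orient_sign <- function(scores, y) {
  if (mean(scores[y == "case"]) < mean(scores[y == "control"])) -1 else 1
}

#' Fit a registry classifier on a feature matrix
#'
#' @param spec a [clf_spec()].
#' @param fm a `tcr_features` training matrix with both classes present.
#' @return object of class `tcr_model` supporting [predict_scores()] and,
#'   for models with an intrinsic ranking signal, [model_feature_importance()].
#' @export
fit_classifier <- function(spec, fm) {
  stopifnot(inherits(spec, "clf_spec"))
  y <- labels_to_y(feature_labels(fm))
  if (nlevels(droplevels(y)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  x <- unclass(fm)
  attr(x, "labels") <- NULL
  hyper <- utils::modifyList(default_hyper[[spec$name]], spec$hyper)
  entry <- .registry[[spec$name]]
  set.seed(spec$seed)
  fit <- entry$fit(x, y, hyper)
  structure(list(name = spec$name, spec = spec, fit = fit,
                 features = colnames(x), type = entry$type),
            class = "tcr_model")
}

#' Continuous case-scores from a fitted model
#'
#' @param model a `tcr_model`.
#' @param newdata a `tcr_features` or plain matrix sharing the training
#'   feature names.
#' @return numeric score per row (case probability or signed margin).
#' @export
predict_scores <- function(model, newdata) {
  x <- if (inherits(newdata, "tcr_features")) unclass(newdata) else newdata
  attr(x, "labels") <- NULL
  if (!identical(colnames(x), model$features)) {
    if (!all(model$features %in% colnames(x)))
      stop("newdata lacks training features", call. = FALSE)
    x <- x[, model$features, drop = FALSE]
  }
  as.numeric(.registry[[model$name]]$predict(model$fit, x))
}

#' Intrinsic feature-importance / ranking signal of a fitted model
#'
#' @param model a `tcr_model`.
#' @return non-negative named vector over the training features, or an error
#'   for models without an intrinsic signal (kNN, naive Bayes, kernel SVM,
#'   MLP, calibrated SVM).
#' @export
model_feature_importance <- function(model) {
  f <- .registry[[model$name]]$importance
  if (is.null(f))
    stop("classifier '", model$name, "' has no intrinsic ranking signal",
         call. = FALSE)
  imp <- f(model$fit, model$features)
  out <- stats::setNames(rep(0, length(model$features)), model$features)
  out[names(imp)] <- pmax(imp, 0)
  out
}

#' @export
print.tcr_model <- function(x, ...) {
  cat(sprintf("<tcr_model> %s on %d features (%s scores)\n",
              x$name, length(x$features), x$type))
  invisible(x)
}

# ---- registry entries -------------------------------------------------------

fit_glm_quiet <- function(df) {
  suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
}

.registry <- list(

  logistic = list(
    type = "prob",
    fit = function(x, y, h) {
      df <- as.data.frame(x); df$.y <- y
      fit_glm_quiet(df)
    },
    predict = function(fit, x) {
      suppressWarnings(stats::predict(fit, as.data.frame(x), type = "response"))
    },
    importance = function(fit, feats) {
      co <- stats::coef(fit)[-1]
      co[is.na(co)] <- 0
      stats::setNames(abs(co), feats)
    }
  ),

  lda = list(
    type = "prob",
    fit = function(x, y, h) {
      xs <- drop_constant(x)
      # tiny seeded jitter keeps the pooled within-class covariance
      # nonsingular when a feature perfectly separates the classes (zero
      # within-group variance), without disturbing the discriminant
      xj <- xs + matrix(stats::rnorm(length(xs), sd = 1e-6), nrow(xs))
      list(fit = suppressWarnings(MASS::lda(xj, grouping = y, tol = 1e-9)),
           cols = colnames(xs))
    },
    predict = function(fit, x) {
      stats::predict(fit$fit, x[, fit$cols, drop = FALSE])$posterior[, "case"]
    },
    importance = function(fit, feats) {
      stats::setNames(abs(fit$fit$scaling[, 1]), fit$cols)
    }
  ),

  svm_linear = list(
    type = "margin",
    fit = function(x, y, h) {
      std <- std_params(x)
      m <- e1071::svm(std_apply(x, std), y, kernel = "linear", cost = h$cost,
                      scale = FALSE)
      dv <- svm_decision(m, std_apply(x, std))
      list(fit = m, std = std, sign = orient_sign(dv, y))
    },
    predict = function(fit, x) {
      fit$sign * svm_decision(fit$fit, std_apply(x, fit$std))
    },
    importance = function(fit, feats) {
      w <- crossprod(fit$fit$coefs, fit$fit$SV)[1, ]
      stats::setNames(abs(w), colnames(fit$fit$SV))
    }
  ),

  svm_poly = list(
    type = "margin",
    fit = function(x, y, h) {
      std <- std_params(x)
      m <- e1071::svm(std_apply(x, std), y, kernel = "polynomial",
                      degree = h$degree, cost = h$cost, scale = FALSE,
                      coef0 = 1)
      dv <- svm_decision(m, std_apply(x, std))
      list(fit = m, std = std, sign = orient_sign(dv, y))
    },
    predict = function(fit, x) {
      fit$sign * svm_decision(fit$fit, std_apply(x, fit$std))
    },
    importance = NULL
  ),

  naive_bayes = list(
    type = "prob",
    fit = function(x, y, h) {
      e1071::naiveBayes(as.data.frame(x), y, laplace = h$laplace)
    },
    predict = function(fit, x) {
      stats::predict(fit, as.data.frame(x), type = "raw")[, "case"]
    },
    importance = NULL
  ),

  decision_tree = list(
    type = "prob",
    fit = function(x, y, h) {
      df <- as.data.frame(x); df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    predict = function(fit, x) {
      stats::predict(fit, as.data.frame(x), type = "prob")[, "case"]
    },
    importance = function(fit, feats) {
      imp <- fit$variable.importance
      if (is.null(imp)) stats::setNames(rep(0, length(feats)), feats) else imp
    }
  ),

  knn = list(
    type = "prob",
    fit = function(x, y, h) list(x = x, y = y, k = h$k),
    predict = function(fit, x) {
      k <- min(fit$k, nrow(fit$x))
      pred <- class::knn(fit$x, x, fit$y, k = k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "case", p, 1 - p)
    },
    importance = NULL
  ),

  random_forest = list(
    type = "prob",
    fit = function(x, y, h) {
      randomForest::randomForest(x, y, ntree = h$ntree)
    },
    predict = function(fit, x) {
      stats::predict(fit, x, type = "prob")[, "case"]
    },
    importance = function(fit, feats) {
      randomForest::importance(fit)[, "MeanDecreaseGini"]
    }
  ),

  gbdt = list(
    type = "prob",
    fit = function(x, y, h) xgb_fit(x, y, h, tree_method = "exact"),
    predict = function(fit, x) xgb_predict(fit, x),
    importance = function(fit, feats) xgb_importance(fit, feats)
  ),

  xgboost_like = list(
    type = "prob",
    fit = function(x, y, h) xgb_fit(x, y, h, tree_method = "hist"),
    predict = function(fit, x) xgb_predict(fit, x),
    importance = function(fit, feats) xgb_importance(fit, feats)
  ),

  adaboost = list(
    type = "margin",
    fit = function(x, y, h) adaboost_fit(x, y, n_estimators = h$n_estimators),
    predict = function(fit, x) adaboost_margin(fit, x),
    importance = function(fit, feats) adaboost_importance(fit, feats)
  ),

  bagging = list(
    type = "prob",
    fit = function(x, y, h) {
      df <- as.data.frame(x); df$.y <- y
      trees <- lapply(seq_len(h$n_estimators), function(i) {
        idx <- sample.int(nrow(df), replace = TRUE)
        rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class")
      })
      list(trees = trees)
    },
    predict = function(fit, x) {
      df <- as.data.frame(x)
      p <- vapply(fit$trees,
                  function(tr) stats::predict(tr, df, type = "prob")[, "case"],
                  numeric(nrow(df)))
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      rowMeans(p)
    },
    importance = function(fit, feats) {
      acc <- stats::setNames(rep(0, length(feats)), feats)
      for (tr in fit$trees) {
        imp <- tr$variable.importance
        if (!is.null(imp)) acc[names(imp)] <- acc[names(imp)] + imp
      }
      acc / length(fit$trees)
    }
  ),

  mlp = list(
    type = "prob",
    fit = function(x, y, h) {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
      xs <- scale(x, center = ctr, scale = scl)
      fit <- nnet::nnet(xs, as.numeric(y == "case"), size = h$size,
                        decay = h$decay, maxit = h$maxit, entropy = TRUE,
                        trace = FALSE)
      list(fit = fit, center = ctr, scale = scl)
    },
    predict = function(fit, x) {
      xs <- scale(x, center = fit$center, scale = fit$scale)
      as.numeric(stats::predict(fit$fit, xs))
    },
    importance = NULL
  ),

  calibrated_cv = list(
    type = "prob",
    fit = function(x, y, h) calibrated_svm_fit(x, y, h),
    predict = function(fit, x) calibrated_svm_predict(fit, x),
    importance = NULL
  )
)

# per-model standardization fitted on the training matrix only
std_params <- function(x) {
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = colMeans(x), scale = scl)
}

std_apply <- function(x, std) {
  out <- scale(x, center = std$center, scale = std$scale)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

svm_decision <- function(m, x) {
  attr(stats::predict(m, x, decision.values = TRUE), "decision.values")[, 1]
}

# ---- xgboost helpers --------------------------------------------------------

xgb_fit <- function(x, y, h, tree_method) {
  params <- list(objective = "binary:logistic", eta = h$eta,
                 max_depth = h$max_depth, tree_method = tree_method,
                 nthread = 1, seed = sample.int(1e6, 1))
  if (!is.null(h$lambda)) params$lambda <- h$lambda
  d <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "case"), nthread = 1)
  xgboost::xgb.train(params = params, data = d, nrounds = h$nrounds,
                     verbose = 0)
}

xgb_predict <- function(fit, x) {
  stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
}

xgb_importance <- function(fit, feats) {
  imp <- tryCatch(xgboost::xgb.importance(model = fit), error = function(e) NULL)
  out <- stats::setNames(rep(0, length(feats)), feats)
  if (!is.null(imp) && nrow(imp) > 0) out[imp$Feature] <- imp$Gain
  out
}

# ---- AdaBoost with decision stumps (discrete SAMME) -------------------------
# Hand-rolled because no boosted-stump package ships with the environment;
# stumps are exact single-split threshold classifiers.

stump_fit <- function(x, y01, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]; ys <- y01[ord]; ws <- w[ord]
    # candidate thresholds between distinct values
    distinct <- which(diff(vs) > 0)
    if (!length(distinct)) next
    thr <- (vs[distinct] + vs[distinct + 1]) / 2
    # cumulative weighted positives/negatives left of each threshold
    wp <- cumsum(ws * ys); wn <- cumsum(ws * (1 - ys))
    tp <- sum(ws * ys); tn <- sum(ws * (1 - ys))
    # polarity +1: predict 1 when v > thr  -> err = wp[left] + (tn - wn[left])
    err_pos <- wp[distinct] + (tn - wn[distinct])
    # polarity -1: predict 1 when v <= thr
    err_neg <- wn[distinct] + (tp - wp[distinct])
    for (s in c(1, -1)) {
      errs <- if (s == 1) err_pos else err_neg
      i <- which.min(errs)
      if (errs[i] < best$err) {
        best <- list(err = errs[i], feature = j, threshold = thr[i],
                     polarity = s)
      }
    }
  }
  best
}

stump_predict <- function(st, x) {
  v <- x[, st$feature]
  if (st$polarity == 1) as.numeric(v > st$threshold)
  else as.numeric(v <= st$threshold)
}

adaboost_fit <- function(x, y, n_estimators = 50) {
  y01 <- as.numeric(y == "case")
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    st <- stump_fit(x, y01, w)
    if (!is.finite(st$err)) break
    err <- max(st$err, 1e-10)
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    pred <- stump_predict(st, x)
    miss <- as.numeric(pred != y01)
    w <- w * exp(alpha * (2 * miss - 1))
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
  }
  if (!length(stumps)) {  # unsplittable data: constant majority margin
    return(list(stumps = list(), alphas = numeric(0),
                const = mean(y01) - 0.5))
  }
  list(stumps = stumps, alphas = alphas, const = 0)
}

adaboost_margin <- function(fit, x) {
  if (!length(fit$stumps)) return(rep(fit$const, nrow(x)))
  h <- vapply(fit$stumps, function(st) 2 * stump_predict(st, x) - 1,
              numeric(nrow(x)))
  if (is.null(dim(h))) h <- matrix(h, nrow = nrow(x))
  as.numeric(h %*% fit$alphas)
}

adaboost_importance <- function(fit, feats) {
  acc <- stats::setNames(rep(0, length(feats)), feats)
  for (i in seq_along(fit$stumps)) {
    f <- feats[fit$stumps[[i]]$feature]
    acc[f] <- acc[f] + fit$alphas[i]
  }
  acc
}

# ---- cross-validated Platt-calibrated linear SVM ----------------------------

calibrated_svm_fit <- function(x, y, h) {
  std <- std_params(x)
  xs <- std_apply(x, std)
  folds <- make_folds(y, k = min(h$folds, min(table(y))), seed = NULL)
  dec <- rep(NA_real_, nrow(x))
  for (f in folds) {
    m <- e1071::svm(xs[-f, , drop = FALSE], y[-f], kernel = "linear",
                    cost = h$cost, scale = FALSE)
    s <- orient_sign(svm_decision(m, xs[-f, , drop = FALSE]), y[-f])
    dec[f] <- s * svm_decision(m, xs[f, , drop = FALSE])
  }
  calib <- suppressWarnings(
    stats::glm(I(y == "case") ~ dec, family = stats::binomial(),
               data = data.frame(dec = dec))
  )
  final <- e1071::svm(xs, y, kernel = "linear", cost = h$cost, scale = FALSE)
  list(svm = final, std = std,
       sign = orient_sign(svm_decision(final, xs), y), calib = calib)
}

calibrated_svm_predict <- function(fit, x) {
  dv <- fit$sign * svm_decision(fit$svm, std_apply(x, fit$std))
  suppressWarnings(
    stats::predict(fit$calib, data.frame(dec = dv), type = "response")
  )
}

# stratified k-fold assignment; returns list of index vectors (test folds)
make_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- seq_along(y)
  folds <- vector("list", k)
  for (cl in unique(y)) {
    members <- sample(idx[y == cl])
    assign_to <- rep(seq_len(k), length.out = length(members))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], members[assign_to == f])
    }
  }
  lapply(folds, sort)
}
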