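#' Randomly assign samples to cross-validation folds
#'
#' Fold sizes differ by at most one; with classification labels the split
#' is additionally stratified so that each class's per-fold counts also
#' differ by at most one. Deterministic given the seed.
#'
#' @param n_samples Number of samples.
#' @param k Number of folds (2..n_samples).
#' @param labels Optional +1/-1 labels for stratification.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in 1..k.
#' @export
random_folds <- function(n_samples, k, labels = NULL, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop_mvpa("need at least 2 folds")
  if (k > n_samples) stop_mvpa("K = ", k, " exceeds the ", n_samples, " samples")
  groups <- if (is.null(labels)) list(seq_len(n_samples))
            else split(seq_len(n_samples), labels)
  fold <- integer(n_samples)
  withr::with_seed(seed, {
    offset <- 0L
    for (g in groups) {
      g <- g[sample.int(length(g))]
      # continuing the cyclic assignment across classes keeps overall fold
      # sizes within 1 even when several classes leave remainders
      fold[g] <- ((offset + seq_along(g) - 1L) %% k) + 1L
      offset <- offset + length(g)
    }
  })
  fold
}

# Core engine: one train/test pass per fold with leakage-safe
# preprocessing. `light = TRUE` skips weight extraction and tibble
# assembly (used by searchlight and permutation loops).
cv_engine <- function(data, labels, folds, model, preprocess = NULL,
                      seed = 1L, light = FALSE) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (length(labels) != n) stop_mvpa("labels length does not match rows")
  folds <- validate_folds(folds)
  if (length(folds) != n) stop_mvpa("folds length does not match rows")
  k <- max(folds)
  classify <- model$task == "classify"
  pred <- numeric(n); dv <- numeric(n); prob <- rep(NA_real_, n)
  fold_w <- if (!light) vector("list", k)
  collect_w <- FALSE
  for (f in seq_len(k)) {
    tr <- folds != f
    ytr <- labels[tr]
    if (classify && length(unique(ytr)) < 2L)
      stop_mvpa("training split for fold ", f, " is missing a class")
    fseed <- derive_seed(seed, f)
    Xtr <- data[tr, , drop = FALSE]
    Xte <- data[!tr, , drop = FALSE]
    pp <- NULL
    if (!is.null(preprocess) && length(preprocess) > 0L) {
      pp <- fit_pipeline(Xtr, ytr, preprocess, seed = fseed)
      Xtr <- pp$train
      Xte <- apply_pipeline(pp, Xte)
    }
    m <- fit_model(model, Xtr, ytr, seed = fseed)
    pr <- predict_model(m, Xte)
    pred[!tr] <- pr$.pred
    dv[!tr] <- pr$decision_value
    prob[!tr] <- pr$probability
    if (!light) {
      lw <- tryCatch(linear_weights(m), error = function(e) NULL)
      if (!is.null(lw)) {
        if (!is.null(pp)) lw <- backproject_weights(pp, lw$w, lw$b, ncol(data))
        fold_w[[f]] <- lw
        collect_w <- TRUE
      }
    }
  }
  list(pred = pred, dv = dv, prob = prob, actual = labels, folds = folds,
       k = k, weights = if (!light && collect_w) fold_w, classify = classify)
}

pooled_statistic <- function(eng) {
  if (eng$classify) mean(eng$pred == eng$actual)
  else stats::cor(eng$pred, eng$actual)
}

confusion_counts <- function(pred, actual) {
  c(tp = sum(pred == 1 & actual == 1),
    tn = sum(pred == -1 & actual == -1),
    fp = sum(pred == 1 & actual == -1),
    fn = sum(pred == -1 & actual == 1))
}

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+FN+TN+FP)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`. The positive class is +1 (e.g. patients).
#' When a denominator is zero the metric is undefined and reported as `NA`,
#' never coerced to 0.
#'
#' @param tp,tn,fp,fn Confusion counts, or a named vector passed as `tp`.
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (length(tp) == 4L && is.null(tn)) {
    cc <- tp
    tp <- cc[["tp"]]; tn <- cc[["tn"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
  }
  total <- tp + tn + fp + fn
  if (total <= 0) stop_mvpa("no samples in the confusion counts")
  tibble::tibble(
    accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' ROC curve and AUC from pooled decision values
#'
#' Sweeps a threshold over the pooled out-of-fold decision values (one
#' curve per analysis, not per fold).
#'
#' @param decision_values Numeric scores, larger favoring class +1.
#' @param labels True labels (+1/-1); both classes must be present.
#' @return List with `curve` (tibble: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(decision_values, labels) {
  if (length(unique(labels)) < 2L)
    stop_mvpa("ROC needs both classes among the labels")
  r <- pROC::roc(response = factor(labels, levels = c(-1, 1)),
                 predictor = as.numeric(decision_values),
                 levels = c("-1", "1"), direction = "<", quiet = TRUE)
  list(
    curve = tibble::tibble(threshold = r$thresholds,
                           fpr = 1 - r$specificities,
                           tpr = r$sensitivities),
    auc = as.numeric(r$auc)
  )
}

#' Prediction precision of a regression analysis
#'
#' Pearson correlation between pooled out-of-fold predicted scores and the
#' true scores.
#'
#' @param predicted,actual Numeric vectors (>= 3 pairs, nonzero variance).
#' @return Correlation coefficient.
#' @export
prediction_precision <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(predicted) < 3L)
    stop_mvpa("need at least 3 prediction pairs")
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0)
    stop_mvpa("undefined correlation: zero variance")
  stats::cor(predicted, actual)
}

#' Run a cross-validated decoding or regression analysis
#'
#' For each fold the preprocessing steps are fitted on the training split
#' only, both splits transformed, the model fitted, and the held-out fold
#' predicted; every sample is predicted exactly once. Classification
#' metrics are computed from confusion counts pooled over folds (the
#' unweighted mean of per-fold accuracies is also reported); ROC/AUC uses
#' pooled decision values; regression performance is the Pearson
#' correlation of pooled predictions with the true scores. Linear models
#' also yield per-fold weight vectors, projected back to the original
#' feature space, and their elementwise mean.
#'
#' @param data Samples-by-features matrix (geometry optional, via
#'   [feature_space()]).
#' @param labels +1/-1 labels (classification) or continuous scores.
#' @param folds Integer fold assignment in 1..K, e.g. from [random_folds()].
#' @param model A [make_model()] spec.
#' @param preprocess Optional list of [step_zscore()], [step_pca()],
#'   [step_select()] steps, applied in order.
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `mvpa_cv`; see [tidy.mvpa_cv()],
#'   [glance.mvpa_cv()], [autoplot.mvpa_cv()].
#' @export
run_cv <- function(data, labels, folds, model = make_model("svm"),
                   preprocess = NULL, seed = 1L) {
  eng <- cv_engine(data, labels, folds, model, preprocess, seed)
  n <- length(eng$pred)
  predictions <- tibble::tibble(
    sample = seq_len(n),
    fold = eng$folds,
    actual = eng$actual,
    predicted = eng$pred,
    decision_value = eng$dv,
    probability = eng$prob
  )
  weights <- NULL
  if (!is.null(eng$weights)) {
    wmat <- do.call(rbind, lapply(eng$weights, `[[`, "w"))
    weights <- list(per_fold = wmat, mean = colMeans(wmat),
                    b_per_fold = vapply(eng$weights, `[[`, numeric(1), "b"))
  }
  if (eng$classify) {
    per_fold <- do.call(rbind, lapply(seq_len(eng$k), function(f) {
      i <- eng$folds == f
      cc <- confusion_counts(eng$pred[i], eng$actual[i])
      cbind(tibble::tibble(fold = f, n_test = sum(i),
                           tp = cc[["tp"]], tn = cc[["tn"]],
                           fp = cc[["fp"]], fn = cc[["fn"]]),
            confusion_metrics(cc))
    }))
    cc <- confusion_counts(eng$pred, eng$actual)
    metrics <- confusion_metrics(cc)
    roc <- roc_auc(eng$dv, eng$actual)
    metrics$auc <- roc$auc
    metrics$accuracy_fold_mean <- mean(per_fold$accuracy)
    out <- list(task = "classify", predictions = predictions,
                per_fold = per_fold, counts = cc, metrics = metrics,
                roc = roc, weights = weights)
  } else {
    per_fold <- do.call(rbind, lapply(seq_len(eng$k), function(f) {
      i <- eng$folds == f
      tibble::tibble(
        fold = f, n_test = sum(i),
        r = if (sum(i) >= 3 && stats::sd(eng$pred[i]) > 0 &&
                stats::sd(eng$actual[i]) > 0)
          stats::cor(eng$pred[i], eng$actual[i]) else NA_real_
      )
    }))
    metrics <- tibble::tibble(
      r = prediction_precision(eng$pred, eng$actual),
      mse = mean((eng$pred - eng$actual)^2)
    )
    out <- list(task = "regress", predictions = predictions,
                per_fold = per_fold, metrics = metrics, weights = weights)
  }
  out$model <- model
  out$seed <- seed
  out$space <- feature_space(data)
  structure(out, class = "mvpa_cv")
}

#' @export
print.mvpa_cv <- function(x, ...) {
  cat(sprintf("<mvpa_cv> %s, %d folds, %d samples\n", x$task,
              max(x$predictions$fold), nrow(x$predictions)))
  if (x$task == "classify") {
    m <- x$metrics
    cat(sprintf("  accuracy %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f\n",
                m$accuracy, m$sensitivity, m$specificity, m$auc))
  } else {
    cat(sprintf("  prediction precision r = %.3f\n", x$metrics$r))
  }
  invisible(x)
}
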