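# Multimodal data fusion: feature-level concatenation or decision-level
# confidence-weighted voting.

#' Declare one feature block for fusion
#'
#' @param name Block name (used in reports and error messages).
#' @param data Samples-by-features matrix for this data type.
#' @param normalize `"none"` (default — measures already on comparable
#'   scales, e.g. fALFF and FC both in \[-1, 1\]) or `"zscore"` to z-score
#'   each column of the block before concatenation (recommended when the
#'   blocks live on very different ranges).
#' @return An object of class `feature_block`.
#' @export
feature_block <- function(name, data, normalize = c("none", "zscore")) {
  structure(
    list(name = name, data = as.matrix(data), normalize = match.arg(normalize),
         space = feature_space(data)),
    class = "feature_block"
  )
}

#' Concatenate feature blocks into one fused matrix
#'
#' Columns are the blocks' columns in the given order; blocks requesting it
#' are column-z-scored first. The fused space is tabular (geometry is
#' lost), but a block-to-column-range index is attached as attribute
#' `"block_index"` so fused weight vectors can be split back per block.
#'
#' @param blocks List of [feature_block()]s sharing sample count and order.
#' @return Fused matrix `n x (p1 + p2 + ...)`.
#' @export
concatenate_features <- function(blocks) {
  if (length(blocks) < 1L) stop_mvpa("no blocks given")
  ns <- vapply(blocks, function(b) nrow(b$data), integer(1))
  if (length(unique(ns)) != 1L)
    stop_mvpa("sample-count mismatch between blocks: ",
              paste(sprintf("%s (n=%d)",
                            vapply(blocks, `[[`, character(1), "name"), ns),
                    collapse = ", "))
  mats <- lapply(blocks, function(b) {
    x <- b$data
    if (b$normalize == "zscore") {
      s <- colsd_pop(x)
      x <- sweep(x, 2L, colMeans(x))
      x <- sweep(x, 2L, ifelse(s > 0, s, 1), "/")
      x[, s == 0] <- 0
    }
    x
  })
  fused <- do.call(cbind, mats)
  ends <- cumsum(vapply(mats, ncol, integer(1)))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  index <- Map(function(s, e) s:e, starts, ends)
  names(index) <- vapply(blocks, `[[`, character(1), "name")
  attr(fused, "block_index") <- index
  set_space(fused, NULL)
}

#' Fuse per-model decisions by confidence-weighted voting
#'
#' Classification: each model's vote is its own decision value (sign =
#' vote, magnitude = confidence on the unified scale), and the fused
#' decision value is their sum; the fused class is its sign, with an exact
#' tie going to +1. Regression: the fused prediction is the unweighted mean
#' of the models' predicted values.
#'
#' @param decisions List (>= 2) of prediction tibbles from [predict_model()]
#'   or the `predictions` element of [run_cv()] results, all for the same
#'   samples in the same order.
#' @param task `"classify"` or `"regress"`.
#' @return Tibble with fused `.pred` and `decision_value`.
#' @export
vote <- function(decisions, task = c("classify", "regress")) {
  task <- match.arg(task)
  if (length(decisions) < 2L) stop_mvpa("voting needs at least 2 models")
  ns <- vapply(decisions, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop_mvpa("mismatched sample sets: models predicted ",
              paste(ns, collapse = ", "), " samples")
  dv <- rowSums(do.call(cbind, lapply(decisions,
                                      function(d) as.numeric(d$decision_value))))
  if (task == "classify") {
    tibble::tibble(.pred = ifelse(dv >= 0, 1, -1), decision_value = dv)
  } else {
    v <- dv / length(decisions)
    tibble::tibble(.pred = v, decision_value = v)
  }
}

#' Cross-validated multimodal fusion analysis
#'
#' `strategy = "concatenate"`: one [run_cv()] on the fused feature matrix.
#' `strategy = "vote"`: one [run_cv()] per block with identical folds, then
#' per-sample confidence-weighted voting of the out-of-fold decisions;
#' metrics are recomputed from the fused predictions.
#'
#' @inheritParams run_cv
#' @param blocks List of [feature_block()]s.
#' @param strategy `"concatenate"` or `"vote"`.
#' @param models For `"vote"`, optionally a list of [make_model()] specs,
#'   one per block (default: the same `model` for every block).
#' @return An `mvpa_cv` object; for `"vote"` it carries `block_results`
#'   (the per-block `mvpa_cv` objects).
#' @export
run_fusion <- function(blocks, labels, folds,
                       strategy = c("concatenate", "vote"),
                       model = make_model("svm"), models = NULL,
                       preprocess = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  folds <- validate_folds(folds)
  if (strategy == "concatenate") {
    fused <- concatenate_features(blocks)
    res <- run_cv(fused, labels, folds, model = model,
                  preprocess = preprocess, seed = seed)
    res$strategy <- "concatenate"
    res$block_index <- attr(fused, "block_index")
    return(res)
  }
  if (length(blocks) < 2L) stop_mvpa("voting needs at least 2 blocks")
  if (is.null(models)) models <- rep(list(model), length(blocks))
  if (length(models) != length(blocks))
    stop_mvpa("need one model spec per block")
  block_results <- Map(function(b, m) {
    run_cv(b$data, labels, folds, model = m, preprocess = preprocess,
           seed = seed)
  }, blocks, models)
  task <- models[[1]]$task
  fused <- vote(lapply(block_results, `[[`, "predictions"), task = task)
  n <- nrow(fused)
  predictions <- tibble::tibble(
    sample = seq_len(n), fold = folds, actual = labels,
    predicted = fused$.pred, decision_value = fused$decision_value,
    probability = NA_real_
  )
  if (task == "classify") {
    per_fold <- do.call(rbind, lapply(seq_len(max(folds)), function(f) {
      i <- folds == f
      cc <- confusion_counts(fused$.pred[i], labels[i])
      cbind(tibble::tibble(fold = f, n_test = sum(i),
                           tp = cc[["tp"]], tn = cc[["tn"]],
                           fp = cc[["fp"]], fn = cc[["fn"]]),
            confusion_metrics(cc))
    }))
    cc <- confusion_counts(fused$.pred, labels)
    metrics <- confusion_metrics(cc)
    roc <- roc_auc(fused$decision_value, labels)
    metrics$auc <- roc$auc
    metrics$accuracy_fold_mean <- mean(per_fold$accuracy)
    out <- list(task = task, predictions = predictions, per_fold = per_fold,
                counts = cc, metrics = metrics, roc = roc, weights = NULL)
  } else {
    metrics <- tibble::tibble(
      r = prediction_precision(fused$.pred, labels),
      mse = mean((fused$.pred - labels)^2)
    )
    out <- list(task = task, predictions = predictions, per_fold = NULL,
                metrics = metrics, weights = NULL)
  }
  out$model <- models
  out$seed <- seed
  out$strategy <- "vote"
  out$block_results <- block_results
  structure(out, class = "mvpa_cv")
}
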