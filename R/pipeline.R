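# Preprocessing pipelines: an ordered list of steps, each fitted on the
# training split only and applied unchanged to held-out data. All steps are
# affine (or column subsets), so linear model weights can be projected back
# to the original feature space for weight maps.

#' Pipeline step: Z-score transform
#' @param direction `"columns"` (fit on train) or `"rows"` (per-sample).
#' @return A pipeline step for use in `preprocess = list(...)`.
#' @seealso [zscore_fit_apply()]
#' @export
step_zscore <- function(direction = c("columns", "rows")) {
  structure(list(step = "zscore", direction = match.arg(direction)),
            class = "mvpa_step")
}

#' Pipeline step: PCA dimension reduction
#' @inheritParams pca_fit
#' @return A pipeline step.
#' @seealso [pca_fit()]
#' @export
step_pca <- function(var_threshold = 0.95, n_components = NULL) {
  structure(list(step = "pca", var_threshold = var_threshold,
                 n_components = n_components),
            class = "mvpa_step")
}

#' Pipeline step: feature selection
#'
#' `"fscore"` and `"weight"` rank features on the training split and keep
#' the top `n` (or `fraction`); `"lasso"` keeps the features with nonzero
#' L1-penalized coefficients (the amount is implied by the penalty).
#'
#' @param method `"fscore"`, `"weight"`, or `"lasso"`.
#' @param n,fraction Amount of features to keep (ranking methods; exactly
#'   one of the two).
#' @param model Linear model spec used by `method = "weight"`.
#' @param inner_folds,lambda LASSO controls, see [lasso_select()].
#' @return A pipeline step.
#' @export
step_select <- function(method = c("fscore", "weight", "lasso"),
                        n = NULL, fraction = NULL, model = NULL,
                        inner_folds = 10L, lambda = NULL) {
  method <- match.arg(method)
  if (method != "lasso" && is.null(n) == is.null(fraction))
    stop_mvpa("give exactly one of n= or fraction= for method '", method, "'")
  structure(list(step = "select", method = method, n = n, fraction = fraction,
                 model = model, inner_folds = inner_folds, lambda = lambda),
            class = "mvpa_step")
}

fit_pipeline <- function(train, y, steps, seed = 1L) {
  fitted <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (!inherits(st, "mvpa_step"))
      stop_mvpa("preprocess must be a list of step_*() objects")
    fitted[[i]] <- switch(st$step,
      zscore = {
        z <- zscore_fit_apply(train, direction = st$direction)
        train <- z$train
        list(step = "zscore", params = z$params)
      },
      pca = {
        pp <- pca_fit(train, var_threshold = st$var_threshold,
                      n_components = st$n_components)
        train <- pca_apply(pp, train)
        list(step = "pca", params = pp)
      },
      select = {
        p_before <- ncol(train)
        sel <- if (st$method == "lasso") {
          lasso_select(train, y, inner_folds = st$inner_folds,
                       lambda = st$lambda, seed = derive_seed(seed, 31L + i))
        } else {
          scores <- if (st$method == "fscore") fscore_rank(train, y)
                    else weight_rank(train, y,
                                     model = st$model %||% make_model(
                                       "svm",
                                       task = if (all(y %in% c(-1, 1))) "classify" else "regress"),
                                     seed = derive_seed(seed, 61L + i))
          select_features(scores, n = st$n, fraction = st$fraction)
        }
        train <- train[, sel, drop = FALSE]
        list(step = "select", selected = as.integer(sel),
             scores = attr(sel, "scores"), n_in = p_before)
      }
    )
  }
  list(steps = fitted, train = train)
}

apply_pipeline <- function(fitted, data) {
  for (st in fitted$steps) {
    data <- switch(st$step,
      zscore = zscore_apply(st$params, data),
      pca = pca_apply(st$params, data),
      select = data[, st$selected, drop = FALSE]
    )
  }
  data
}

# Project an affine decision function (w, b) in preprocessed space back to
# the original feature space. Row-direction Z-scoring is a per-sample
# transform with a one-to-one column correspondence, so weights pass
# through unchanged (documented).
backproject_weights <- function(fitted, w, b, p_original) {
  for (st in rev(fitted$steps)) {
    if (st$step == "select") {
      w_full <- numeric(st$n_in)
      w_full[st$selected] <- w
      w <- w_full
    } else if (st$step == "pca") {
      pp <- st$params
      w_orig <- as.numeric(pp$loadings %*% w)
      b <- b - sum(pp$center * w_orig)
      w <- w_orig
    } else if (st$step == "zscore" && st$params$direction == "columns") {
      s <- st$params$sigma
      w_orig <- ifelse(s > 0, w / s, 0)
      b <- b - sum(w_orig * st$params$m)
      w <- w_orig
    }
  }
  if (length(w) != p_original)
    stop_mvpa("internal: backprojected weights have length ", length(w),
              ", expected ", p_original)
  list(w = w, b = b)
}
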