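# Feature preprocessing: every *_fit function sees training data only; the
# fitted parameters are then applied unchanged to held-out data.

#' Z-score features using training-set statistics
#'
#' `Z = (x - m) / sigma` with `m` and `sigma` estimated from the training
#' data only (column direction) and applied to both splits. The population
#' (divide-by-n) standard deviation is used. Constant columns (`sigma = 0`)
#' map to 0 rather than NaN so they stay inert downstream. Row direction
#' normalizes each sample independently with that row's own mean/SD, so it
#' involves no training-set statistics at all.
#'
#' @param train Training matrix (samples x features).
#' @param test Optional held-out matrix transformed with the training
#'   parameters.
#' @param direction `"columns"` (per feature, fitted on train) or `"rows"`
#'   (per sample, self-normalizing).
#' @return List with `train`, `test` (or NULL) and `params`
#'   (`m`, `sigma`, `direction`).
#' @export
zscore_fit_apply <- function(train, test = NULL,
                             direction = c("columns", "rows")) {
  direction <- match.arg(direction)
  if (direction == "columns") {
    if (nrow(train) < 2L)
      stop_mvpa("column-wise Z-scoring needs at least 2 training samples")
    m <- colMeans(train)
    s <- colsd_pop(train)
    params <- list(m = m, sigma = s, direction = direction)
    list(train = zscore_apply(params, train),
         test = if (!is.null(test)) zscore_apply(params, test),
         params = params)
  } else {
    params <- list(m = NULL, sigma = NULL, direction = direction)
    list(train = zscore_apply(params, train),
         test = if (!is.null(test)) zscore_apply(params, test),
         params = params)
  }
}

zscore_apply <- function(params, x) {
  if (params$direction == "columns") {
    s <- params$sigma
    out <- sweep(x, 2L, params$m)
    out <- sweep(out, 2L, ifelse(s > 0, s, 1), "/")
    out[, s == 0] <- 0
    out
  } else {
    m <- rowMeans(x)
    s <- sqrt(rowMeans(sweep(x, 1L, m)^2))
    out <- sweep(x, 1L, m)
    out <- sweep(out, 1L, ifelse(s > 0, s, 1), "/")
    out[s == 0, ] <- 0
    out
  }
}

#' Fit a principal-component reduction on training data
#'
#' Components are the eigenvectors of the column-centered training
#' covariance. The number kept is either explicit (`n_components`) or the
#' smallest n whose cumulative explained-variance fraction reaches
#' `var_threshold` (default 0.95: top n PCs explain >= 95% of total variance
#' while the top n-1 explain less). The count is capped at
#' `min(n_train - 1, n_features)`.
#'
#' @param train Training matrix.
#' @param var_threshold Cumulative explained-variance target in (0, 1].
#' @param n_components Optional explicit number of components.
#' @return List of class `pca_params`: `loadings` (features x kept),
#'   `center`, `explained` (per-component fractions), `n_kept`.
#' @export
pca_fit <- function(train, var_threshold = 0.95, n_components = NULL) {
  if (nrow(train) < 2L) stop_mvpa("PCA needs at least 2 training samples")
  cap <- min(nrow(train) - 1L, ncol(train))
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  var <- pc$sdev^2
  frac <- var / sum(var)
  if (!is.null(n_components)) {
    if (!is_count(n_components) || n_components > cap)
      stop_mvpa("n_components must be an integer between 1 and ", cap,
                " (= min(n_train - 1, n_features))")
    n_kept <- as.integer(n_components)
  } else {
    if (!(var_threshold > 0 && var_threshold <= 1))
      stop_mvpa("var_threshold must be in (0, 1]")
    cum <- cumsum(frac)
    n_kept <- which(cum >= var_threshold - 1e-12)[1]
    if (is.na(n_kept)) n_kept <- cap
    n_kept <- min(as.integer(n_kept), cap)
  }
  structure(
    list(loadings = pc$rotation[, seq_len(n_kept), drop = FALSE],
         center = pc$center,
         explained = frac[seq_len(n_kept)],
         n_kept = n_kept),
    class = "pca_params"
  )
}

#' Project data onto fitted principal components
#'
#' Centers with the training mean and projects onto the kept loadings; on
#' the training data itself this reproduces the fitted scores.
#'
#' @param params A `pca_params` from [pca_fit()].
#' @param data Matrix with the same feature count the PCA was fitted on.
#' @return Score matrix with `n_kept` columns.
#' @export
pca_apply <- function(params, data) {
  if (ncol(data) != nrow(params$loadings))
    stop_mvpa("feature count (", ncol(data), ") does not match the fitted PCA (",
              nrow(params$loadings), ")")
  sweep(data, 2L, params$center) %*% params$loadings
}

#' Rank features by univariate F score
#'
#' Classification: the one-way (equal-variance pooled) ANOVA F comparing the
#' two classes, per feature. Features identical across classes score 0; a
#' feature with distinct class means but zero within-class variance scores
#' `Inf` and sorts above every finite score. Regression (continuous labels):
#' the univariate regression F statistic `(n-2) r^2 / (1 - r^2)`.
#'
#' @param train Training matrix.
#' @param labels Class labels (+1/-1) or continuous scores.
#' @return Numeric vector of per-feature scores.
#' @export
fscore_rank <- function(train, labels) {
  n <- nrow(train)
  if (length(labels) != n) stop_mvpa("labels length does not match rows")
  if (length(unique(labels)) == 2L && all(labels %in% c(-1, 1))) {
    a <- train[labels == 1, , drop = FALSE]
    b <- train[labels == -1, , drop = FALSE]
    if (nrow(a) < 2L || nrow(b) < 2L)
      stop_mvpa("each class needs at least 2 training samples for F scores")
    ma <- colMeans(a); mb <- colMeans(b)
    gm <- colMeans(train)
    msb <- nrow(a) * (ma - gm)^2 + nrow(b) * (mb - gm)^2 # df = 1
    ssw <- colSums(sweep(a, 2L, ma)^2) + colSums(sweep(b, 2L, mb)^2)
    msw <- ssw / (n - 2L)
    f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
    as.numeric(f)
  } else {
    if (n < 3L) stop_mvpa("regression F scores need at least 3 samples")
    y <- as.numeric(labels)
    sx <- colsd_pop(train)
    sy <- sqrt(mean((y - mean(y))^2))
    if (sy == 0) stop_mvpa("labels have zero variance")
    covxy <- colMeans(sweep(train, 2L, colMeans(train)) * (y - mean(y)))
    r <- ifelse(sx > 0, covxy / (sx * sy), 0)
    r2 <- pmin(r^2, 1)
    ifelse(sx == 0, 0, ifelse(r2 >= 1 - 1e-15, Inf, (n - 2) * r2 / (1 - r2)))
  }
}

#' Rank features by the absolute weight of a linear model
#'
#' Fits the given linear-weight-capable model on the training data only and
#' scores each feature by `|w_j|`.
#'
#' @param train Training matrix.
#' @param labels Labels or scores matching the model task.
#' @param model A [make_model()] spec with an affine decision function
#'   (linear-kernel SVM, logistic regression, or LDA).
#' @param seed Seed forwarded to the model fit.
#' @return Numeric vector of per-feature scores.
#' @export
weight_rank <- function(train, labels, model = make_model("svm"), seed = 1L) {
  fitted <- fit_model(model, train, labels, seed = seed)
  abs(linear_weights(fitted)$w)
}

#' Select the top-scoring features
#'
#' Keeps the highest-scoring features, either an exact count `n` or a
#' fraction of all features (`floor(fraction * n_features)`, minimum 1).
#' Ties are broken toward the lower feature index; `Inf` scores sort first.
#'
#' @param scores Per-feature scores (higher = more discriminative).
#' @param n Exact number of features to keep.
#' @param fraction Fraction in (0, 1] of features to keep (alternative to `n`).
#' @return Integer vector of selected feature indices, ordered by descending
#'   score; the scores are attached as attribute `"scores"`.
#' @export
select_features <- function(scores, n = NULL, fraction = NULL) {
  p <- length(scores)
  if (is.null(n) == is.null(fraction))
    stop_mvpa("give exactly one of n= or fraction=")
  if (!is.null(fraction)) {
    if (!(is.numeric(fraction) && length(fraction) == 1L &&
          fraction > 0 && fraction <= 1))
      stop_mvpa("fraction must be in (0, 1]")
    n <- max(1L, floor(fraction * p))
  }
  if (!is_count(n) || n > p)
    stop_mvpa("cannot select ", n, " of ", p, " features")
  ord <- order(-scores, seq_len(p))
  sel <- ord[seq_len(n)]
  attr(sel, "scores") <- scores
  sel
}

#' LASSO feature selection with inner cross-validated lambda
#'
#' L1-penalized least squares `min (1/2N) sum (y_i - w0 - x_i'w)^2 +
#' lambda sum |w_j|`; the penalty is chosen from a 100-value log-spaced grid
#' between the data-derived `lambda_max` (smallest penalty giving the empty
#' model) and `lambda_max * 1e-4` by 10-fold cross-validation *within the
#' training data*, minimizing MSE. Selected features are those with nonzero
#' coefficients at the chosen penalty. Classification labels (+1/-1) are
#' treated as the numeric response of the squared-loss objective.
#'
#' @param train Training matrix.
#' @param y Labels (+1/-1) or continuous scores.
#' @param inner_folds Folds of the inner cross-validation (default 10).
#' @param lambda Optional fixed penalty, bypassing the inner CV.
#' @param seed Seed for the deterministic inner fold assignment (stratified
#'   for classification labels).
#' @return Integer vector of selected feature indices (ascending), with
#'   attributes `"lambda"` and `"coefficients"`.
#' @export
lasso_select <- function(train, y, inner_folds = 10L, lambda = NULL, seed = 1L) {
  y <- as.numeric(y)
  if (is.null(lambda)) {
    if (nrow(train) < inner_folds)
      stop_mvpa("need at least ", inner_folds, " training samples for the inner CV")
    is_cls <- all(y %in% c(-1, 1))
    foldid <- random_folds(nrow(train), inner_folds,
                           labels = if (is_cls) y, seed = seed)
    cvfit <- glmnet::cv.glmnet(train, y, family = "gaussian",
                               type.measure = "mse", foldid = foldid,
                               nlambda = 100, lambda.min.ratio = 1e-4,
                               standardize = TRUE)
    lambda <- cvfit$lambda.min
    co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]
  } else {
    fit <- glmnet::glmnet(train, y, family = "gaussian", lambda = lambda,
                          standardize = TRUE)
    co <- as.numeric(stats::coef(fit))[-1]
  }
  sel <- which(co != 0)
  if (length(sel) == 0L)
    stop_mvpa("empty selection: all LASSO coefficients are zero at lambda = ",
              signif(lambda, 4))
  attr(sel, "lambda") <- lambda
  attr(sel, "coefficients") <- co
  sel
}
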