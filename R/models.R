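# Uniform contract over the seven estimators. Optimization internals are
# delegated to mature backends (libsvm via e1071, rpart, randomForest);
# this module owns defaults, seeding, the unified decision-value scale, and
# linear weight extraction. KNN and two-class LDA are implemented directly
# so that tie-breaking and singularity handling follow the documented
# contracts exactly.

.svm_param_names <- c("type", "kernel", "c", "g", "d", "r", "nu", "p")
.model_params <- list(
  svm = .svm_param_names,
  knn = "k",
  logistic = character(),
  naive_bayes = character(),
  lda = character(),
  tree = character(),
  forest = c("n_trees", "mtry")
)
.regression_capable <- c("svm", "knn", "tree", "forest")

#' Build a model specification with field-standard defaults
#'
#' Defaults: C-SVC with a linear kernel and `c = 1` for classification;
#' epsilon-SVR with a linear kernel, `c = 1`, `p = 0.1` for regression
#' (further SVM parameters `g = 0.1`, `d = 3`, `r = 0`, `nu = 0.5`);
#' `k = 11` nearest neighbors; 500 forest trees. Only SVM, KNN, decision
#' tree and random forest support regression.
#'
#' @param algorithm One of `"svm"`, `"knn"`, `"logistic"`, `"naive_bayes"`,
#'   `"lda"`, `"tree"`, `"forest"`.
#' @param task `"classify"` or `"regress"`.
#' @param ... Parameter overrides, named as in the field (`kernel`, `c`,
#'   `g`, `d`, `r`, `nu`, `p`, `k`, `n_trees`, `mtry`, `type`). Unknown
#'   names are rejected.
#' @return An object of class `mvpa_model_spec`.
#' @export
make_model <- function(algorithm = c("svm", "knn", "logistic", "naive_bayes",
                                     "lda", "tree", "forest"),
                       task = c("classify", "regress"), ...) {
  algorithm <- match.arg(algorithm)
  task <- match.arg(task)
  if (task == "regress" && !(algorithm %in% .regression_capable))
    stop_mvpa("'", algorithm, "' supports classification only; ",
              "regression is available for: ",
              paste(.regression_capable, collapse = ", "))
  overrides <- list(...)
  allowed <- .model_params[[algorithm]]
  unknown <- setdiff(names(overrides), allowed)
  if (length(unknown) > 0L || (length(overrides) > 0L && is.null(names(overrides))))
    stop_mvpa("unknown parameter(s) for ", algorithm, ": ",
              paste(unknown, collapse = ", "),
              if (length(allowed)) paste0(" (allowed: ", paste(allowed, collapse = ", "), ")")
              else " (this algorithm has no tunable parameters here)")
  params <- switch(algorithm,
    svm = list(type = if (task == "classify") "c-svc" else "eps-svr",
               kernel = "linear", c = 1, g = 0.1, d = 3, r = 0, nu = 0.5,
               p = 0.1),
    knn = list(k = 11L),
    forest = list(n_trees = 500L, mtry = NULL),
    list()
  )
  params[names(overrides)] <- overrides
  if (algorithm == "svm") {
    ok <- list(`c-svc` = "classify", `nu-svc` = "classify",
               `eps-svr` = "regress", `nu-svr` = "regress")
    if (is.null(ok[[params$type]]) || ok[[params$type]] != task)
      stop_mvpa("SVM type '", params$type, "' does not match task '", task, "'")
  }
  structure(list(algorithm = algorithm, task = task, params = params),
            class = "mvpa_model_spec")
}

#' @export
print.mvpa_model_spec <- function(x, ...) {
  pr <- x$params[!vapply(x$params, is.null, logical(1))]
  cat(sprintf("<mvpa_model_spec> %s (%s)%s\n", x$algorithm, x$task,
              if (length(pr)) paste0(": ", paste(names(pr), unlist(pr),
                                                 sep = "=", collapse = ", "))
              else ""))
  invisible(x)
}

.e1071_type <- c(`c-svc` = "C-classification", `nu-svc` = "nu-classification",
                 `eps-svr` = "eps-regression", `nu-svr` = "nu-regression")

#' Fit a model to training data
#'
#' Deterministic given `(X, y, spec, seed)`; the forest's resampling uses a
#' seed derived from `seed`. Classification labels must be +1/-1.
#'
#' @param spec A [make_model()] specification.
#' @param X Training matrix (samples x features).
#' @param y Labels (+1/-1) or continuous scores.
#' @param seed Integer seed (used by stochastic algorithms).
#' @return An object of class `mvpa_fit`.
#' @export
fit_model <- function(spec, X, y, seed = 1L) {
  if (!inherits(spec, "mvpa_model_spec")) stop_mvpa("spec must come from make_model()")
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_mvpa("X rows and y length differ")
  if (anyNA(X) || any(!is.finite(y)))
    stop_mvpa("training data contain non-finite values")
  classify <- spec$task == "classify"
  if (classify) {
    if (!all(y %in% c(-1, 1)) || length(unique(y)) != 2L)
      stop_mvpa("classification labels must contain both classes, coded +1/-1")
  }
  p <- spec$params
  fit <- switch(spec$algorithm,
    svm = {
      yy <- if (classify) factor(y, levels = c(-1, 1)) else y
      # inputs are validated finite above, so NA handling can be skipped
      m <- e1071::svm(X, yy, scale = FALSE, type = .e1071_type[[p$type]],
                      kernel = p$kernel, cost = p$c, gamma = p$g,
                      degree = p$d, coef0 = p$r, nu = p$nu, epsilon = p$p,
                      na.action = function(x) x)
      # libsvm orientation: positive decision values favor the class named
      # first in the stored training decision-value column
      flip <- if (classify &&
                  strsplit(colnames(m$decision.values), "/")[[1]][1] != "1")
        -1 else 1
      out <- list(backend = m, flip = flip)
      if (p$kernel == "linear") {
        out$w <- as.numeric(crossprod(m$SV, m$coefs)) * flip
        out$b <- -m$rho * flip
      }
      out
    },
    knn = {
      k <- as.integer(p$k)
      if (k < 1L || k > nrow(X))
        stop_mvpa("k = ", k, " must lie in 1..n_train (", nrow(X), ")")
      list(X = X, y = y, k = k)
    },
    logistic = {
      y01 <- as.integer(y == 1)
      g <- suppressWarnings(
        stats::glm.fit(cbind(`(Intercept)` = 1, X), y01,
                       family = stats::binomial())
      )
      co <- g$coefficients
      co[is.na(co)] <- 0
      list(w = co[-1], b = co[1])
    },
    naive_bayes = {
      df <- as.data.frame(X)
      colnames(df) <- paste0("F", seq_len(ncol(X)))
      m <- e1071::naiveBayes(df, factor(y, levels = c(-1, 1)))
      list(backend = m, colnames = colnames(df))
    },
    lda = fit_lda(X, y),
    tree = {
      df <- as.data.frame(X)
      colnames(df) <- paste0("F", seq_len(ncol(X)))
      df$.y <- if (classify) factor(y, levels = c(-1, 1)) else y
      m <- rpart::rpart(.y ~ ., data = df,
                        method = if (classify) "class" else "anova")
      list(backend = m, colnames = setdiff(colnames(df), ".y"))
    },
    forest = {
      yy <- if (classify) factor(y, levels = c(-1, 1)) else y
      m <- withr::with_seed(
        derive_seed(seed, 4242L),
        if (is.null(p$mtry))
          randomForest::randomForest(X, yy, ntree = p$n_trees)
        else
          randomForest::randomForest(X, yy, ntree = p$n_trees, mtry = p$mtry)
      )
      list(backend = m)
    }
  )
  structure(list(spec = spec, fit = fit, n_features = ncol(X)),
            class = "mvpa_fit")
}

# Two-class Gaussian LDA with pooled within-class covariance. On a singular
# covariance a ridge of 1e-6 * trace/p is added once (with a warning);
# if the system is still unsolvable, the fit fails with advice to reduce
# dimensionality first.
fit_lda <- function(X, y) {
  a <- X[y == 1, , drop = FALSE]
  b <- X[y == -1, , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop_mvpa("LDA needs at least 2 training samples per class")
  mu1 <- colMeans(a); mu2 <- colMeans(b)
  S <- (crossprod(sweep(a, 2L, mu1)) + crossprod(sweep(b, 2L, mu2))) /
    (nrow(X) - 2L)
  d <- mu1 - mu2
  solve_spd <- function(S) chol2inv(chol(S)) %*% d
  w <- tryCatch(solve_spd(S), error = function(e) NULL)
  if (is.null(w)) {
    ridge <- 1e-6 * sum(diag(S)) / ncol(X)
    warning("LDA within-class covariance is singular; added a ridge of ",
            signif(ridge, 3), " to the diagonal", call. = FALSE)
    w <- tryCatch(solve_spd(S + diag(ridge, ncol(X))),
                  error = function(e) NULL)
    if (is.null(w))
      stop_mvpa("LDA covariance is unsolvable even after regularization; ",
                "reduce dimensionality first (e.g. PCA)")
  }
  w <- as.numeric(w)
  b0 <- -sum((mu1 + mu2) / 2 * w) + log(nrow(a) / nrow(b))
  list(w = w, b = b0)
}

#' Predict held-out samples
#'
#' Every model populates a `decision_value` on a sign-coherent scale:
#' SVM, the signed margin; logistic/naive Bayes/tree/forest,
#' `2 * (P(+1) - 0.5)`; LDA, the signed discriminant; KNN,
#' `(votes_+ - votes_-) / k`; regression models, the predicted value
#' itself. The predicted class is the sign of the decision value; an exact
#' tie (decision value 0) deterministically predicts +1.
#'
#' @param model An `mvpa_fit` from [fit_model()].
#' @param X Matrix of test samples (feature count must match training).
#' @return A tibble with one row per sample: `.pred` (class +1/-1 or value),
#'   `decision_value`, and `probability` (P(class +1); NA where the model
#'   provides none).
#' @export
predict_model <- function(model, X) {
  if (!inherits(model, "mvpa_fit")) stop_mvpa("model must come from fit_model()")
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop_mvpa("test data has ", ncol(X), " features; model was trained on ",
              model$n_features)
  spec <- model$spec
  classify <- spec$task == "classify"
  f <- model$fit
  res <- switch(spec$algorithm,
    svm = {
      if (!is.null(f$w)) { # linear kernel: evaluate the affine score directly
        s <- as.numeric(X %*% f$w + f$b)
        if (classify) list(dv = s, prob = rep(NA_real_, nrow(X)))
        else list(value = s)
      } else if (classify) {
        pr <- stats::predict(f$backend, X, decision.values = TRUE)
        dv <- as.numeric(attr(pr, "decision.values")) * f$flip
        list(dv = dv, prob = rep(NA_real_, nrow(X)))
      } else {
        v <- as.numeric(stats::predict(f$backend, X))
        list(value = v)
      }
    },
    knn = predict_knn(f, X, classify),
    logistic = {
      pr <- stats::plogis(as.numeric(X %*% f$w + f$b))
      list(dv = 2 * (pr - 0.5), prob = pr)
    },
    naive_bayes = {
      df <- as.data.frame(X)
      colnames(df) <- f$colnames
      raw <- stats::predict(f$backend, df, type = "raw")
      p1 <- as.numeric(raw[, "1"])
      list(dv = 2 * (p1 - 0.5), prob = p1)
    },
    lda = {
      dv <- as.numeric(X %*% f$w + f$b)
      list(dv = dv, prob = stats::plogis(dv))
    },
    tree = {
      df <- as.data.frame(X)
      colnames(df) <- f$colnames
      if (classify) {
        p1 <- as.numeric(stats::predict(f$backend, df, type = "prob")[, "1"])
        list(dv = 2 * (p1 - 0.5), prob = p1)
      } else {
        list(value = as.numeric(stats::predict(f$backend, df)))
      }
    },
    forest = {
      if (classify) {
        p1 <- as.numeric(stats::predict(f$backend, X, type = "prob")[, "1"])
        list(dv = 2 * (p1 - 0.5), prob = p1)
      } else {
        list(value = as.numeric(stats::predict(f$backend, X)))
      }
    }
  )
  if (classify) {
    tibble::tibble(
      .pred = ifelse(res$dv >= 0, 1, -1),
      decision_value = res$dv,
      probability = res$prob
    )
  } else {
    tibble::tibble(
      .pred = res$value,
      decision_value = res$value,
      probability = NA_real_
    )
  }
}

# Plain Euclidean KNN. The k-th-neighbor distance tie is resolved toward
# the lower training-sample index (order() is stable on the index
# tie-break), making predictions fully deterministic.
predict_knn <- function(f, X, classify) {
  ntr <- nrow(f$X)
  d2 <- outer(rowSums(X^2), rep(1, ntr)) +
    outer(rep(1, nrow(X)), rowSums(f$X^2)) - 2 * X %*% t(f$X)
  if (classify) {
    dv <- numeric(nrow(X)); prob <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      nb <- order(d2[i, ], seq_len(ntr))[seq_len(f$k)]
      vplus <- sum(f$y[nb] == 1)
      dv[i] <- (vplus - (f$k - vplus)) / f$k
      prob[i] <- vplus / f$k
    }
    list(dv = dv, prob = prob)
  } else {
    v <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      nb <- order(d2[i, ], seq_len(ntr))[seq_len(f$k)]
      v[i] <- mean(f$y[nb])
    }
    list(value = v)
  }
}

#' Extract the affine decision function of a linear model
#'
#' For models whose discriminant is affine in the features — linear-kernel
#' SVM/SVR, logistic regression (log-odds), and LDA — returns the weight
#' vector and offset with `score(x) = w . x + b`. For the linear SVM this
#' score *is* the decision value; for logistic regression and LDA it is the
#' affine discriminant whose sign agrees with the bounded decision value.
#'
#' @param model An `mvpa_fit`.
#' @return List with `w` (per-feature weights) and `b` (offset).
#' @export
linear_weights <- function(model) {
  spec <- model$spec
  f <- model$fit
  if (spec$algorithm == "svm") {
    if (spec$params$kernel != "linear")
      stop_mvpa("weights undefined: '", spec$params$kernel,
                "'-kernel SVM has no linear weight vector")
    return(list(w = f$w, b = f$b))
  }
  if (spec$algorithm %in% c("logistic", "lda"))
    return(list(w = as.numeric(f$w), b = as.numeric(f$b)))
  stop_mvpa("weights undefined: '", spec$algorithm,
            "' has no affine decision function")
}
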