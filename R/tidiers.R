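# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result into per-fold rows
#' @param x An `mvpa_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per fold (counts and metrics, or per-fold r).
#' @method tidy mvpa_cv
#' @export
tidy.mvpa_cv <- function(x, ...) tibble::as_tibble(x$per_fold)

#' One-row summary of a cross-validation result
#' @param x An `mvpa_cv` object.
#' @param ... Unused.
#' @return One-row tibble of pooled metrics.
#' @method glance mvpa_cv
#' @export
glance.mvpa_cv <- function(x, ...) tibble::as_tibble(x$metrics)

#' Tidy a permutation test into one row per permutation
#' @param x An `mvpa_permutation` object.
#' @param ... Unused.
#' @return Tibble with `permutation` and `statistic` columns.
#' @method tidy mvpa_permutation
#' @export
tidy.mvpa_permutation <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm), statistic = x$null_samples)
}

#' One-row summary of a permutation test
#' @param x An `mvpa_permutation` object.
#' @param ... Unused.
#' @return Tibble with observed statistic, N, p (numeric count/N) and the
#'   bound flag (p printed as "< 1/N" when set).
#' @method glance mvpa_permutation
#' @export
glance.mvpa_permutation <- function(x, ...) {
  tibble::tibble(observed = x$observed, n_perm = x$n_perm,
                 p_value = x$p$p, p_bound = x$p$bound)
}

#' Tidy a searchlight map into one row per center voxel
#' @param x An `mvpa_searchlight` object.
#' @param ... Unused.
#' @return Tibble with voxel coordinates, sphere size, and the statistic.
#' @method tidy mvpa_searchlight
#' @export
tidy.mvpa_searchlight <- function(x, ...) {
  co <- x$space$coords
  tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3],
                 n_voxels = x$n_voxels, statistic = x$statistic)
}

#' Plot the pooled ROC curve of a classification result
#' @param object An `mvpa_cv` classification result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mvpa_cv
#' @export
autoplot.mvpa_cv <- function(object, ...) {
  if (object$task != "classify" || is.null(object$roc))
    stop_mvpa("autoplot.mvpa_cv draws the ROC curve of a classification result")
  cv <- object$roc$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, color = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  title = sprintf("ROC curve (AUC = %.3f)", object$roc$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution with the observed statistic
#' @param object An `mvpa_permutation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mvpa_permutation
#' @export
autoplot.mvpa_permutation <- function(object, ...) {
  lab <- if (object$task == "classify") "chance-level accuracy" else "null r"
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "#4393c3", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red",
                        linewidth = 1) +
    ggplot2::labs(x = lab, y = "permutations",
                  title = sprintf("Observed %.3f, %s", object$observed,
                                  format(object$p))) +
    ggplot2::theme_minimal()
}

#' Plot axial slices of a searchlight statistic map
#' @param object An `mvpa_searchlight` object.
#' @param ... Unused.
#' @return A ggplot faceted by z slice.
#' @method autoplot mvpa_searchlight
#' @export
autoplot.mvpa_searchlight <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$statistic)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = if (object$task == "classify")
      "Searchlight accuracy map" else "Searchlight prediction-precision map") +
    ggplot2::theme_minimal()
}
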