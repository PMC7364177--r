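#' Permutation p-value with the P < 1/N convention
#'
#' `p = #\{null >= observed\} / N` ("equal to or greater"). When no null
#' sample reaches the observed statistic the p-value is reported as the
#' bound `P < 1/N`, never as 0: the attainable precision is limited by the
#' number of permutations.
#'
#' @param observed Observed statistic.
#' @param null_samples Numeric vector of N null statistics.
#' @return An object of class `perm_pvalue`: `count`, `n`, `p`
#'   (`count/n`; 0 indicates the bound), `bound` (logical).
#' @export
perm_pvalue <- function(observed, null_samples) {
  if (length(null_samples) < 1L) stop_mvpa("empty null distribution")
  count <- sum(null_samples >= observed)
  structure(
    list(count = count, n = length(null_samples),
         p = count / length(null_samples), bound = count == 0L),
    class = "perm_pvalue"
  )
}

#' @export
format.perm_pvalue <- function(x, ...) {
  if (x$bound) sprintf("P < %g (i.e. P < 1/%d)", 1 / x$n, x$n)
  else sprintf("P = %g", x$p)
}

#' @export
print.perm_pvalue <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Permutation test of a cross-validated analysis
#'
#' Builds the null distribution of the aggregate statistic (pooled
#' classification accuracy, or prediction precision for regression) by
#' shuffling the label/score vector N times and re-running the *entire*
#' pipeline — including any training-fold feature selection or PCA — with
#' the fold structure held fixed. Each iteration's shuffle is derived from
#' `(seed, i)`, so the null distribution is reproducible and independent of
#' execution order.
#'
#' @inheritParams run_cv
#' @param n_perm Number of permutations N.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return An object of class `mvpa_permutation`: `observed`,
#'   `null_samples`, `n_perm`, `p` (a [perm_pvalue()]), `seed`, `task`.
#' @export
permutation_test <- function(data, labels, folds, model = make_model("svm"),
                             preprocess = NULL, n_perm = 1000L, seed = 1L,
                             workers = 1L) {
  if (n_perm < 1L) stop_mvpa("n_perm must be >= 1")
  data <- as.matrix(data)
  folds <- validate_folds(folds)
  n <- nrow(data)
  observed <- pooled_statistic(
    cv_engine(data, labels, folds, model, preprocess, seed = seed, light = TRUE)
  )
  one_perm <- function(i) {
    ys <- withr::with_seed(derive_seed(seed, i), labels[sample.int(n)])
    tryCatch(
      pooled_statistic(
        cv_engine(data, ys, folds, model, preprocess,
                  seed = derive_seed(seed, i), light = TRUE)
      ),
      error = function(e) stop_mvpa("permutation ", i, " failed: ",
                                    conditionMessage(e))
    )
  }
  idx <- seq_len(n_perm)
  null_samples <- if (workers > 1L) {
    unlist(parallel::mclapply(idx, one_perm, mc.cores = workers))
  } else {
    vapply(idx, one_perm, numeric(1))
  }
  structure(
    list(observed = observed, null_samples = null_samples,
         n_perm = as.integer(n_perm), p = perm_pvalue(observed, null_samples),
         seed = seed, task = model$task),
    class = "mvpa_permutation"
  )
}

#' @export
print.mvpa_permutation <- function(x, ...) {
  cat(sprintf("<mvpa_permutation> observed %s = %.4f over %d permutations: %s\n",
              if (x$task == "classify") "accuracy" else "r",
              x$observed, x$n_perm, format(x$p)))
  invisible(x)
}

#' Max-statistic family-wise-error correction over searchlight centers
#'
#' For each permutation only the maximum statistic across all centers is
#' kept; every center's observed statistic is then compared against this
#' common null distribution of maxima, which controls the family-wise
#' error of the whole map. The same `>=` counting and `P < 1/N` bound rule
#' apply; corrected p-values are never smaller than the uncorrected ones.
#'
#' @param observed_map Per-center observed statistics.
#' @param permuted_maps N x n_centers matrix: each row one permutation's
#'   full map (computed with the same shuffled labels across centers).
#' @return An object of class `fwe_result`: `max_null`, `corrected_p`,
#'   `corrected_bound`, `uncorrected_p`, `uncorrected_bound`, `n_perm`.
#' @export
fwe_correct <- function(observed_map, permuted_maps) {
  permuted_maps <- as.matrix(permuted_maps)
  if (ncol(permuted_maps) != length(observed_map))
    stop_mvpa("permuted_maps has ", ncol(permuted_maps),
              " centers but observed_map has ", length(observed_map))
  n_perm <- nrow(permuted_maps)
  max_null <- apply(permuted_maps, 1L, max)
  corr_count <- vapply(observed_map, function(o) sum(max_null >= o), numeric(1))
  unc_count <- vapply(seq_along(observed_map),
                      function(j) sum(permuted_maps[, j] >= observed_map[j]),
                      numeric(1))
  structure(
    list(max_null = max_null,
         corrected_p = corr_count / n_perm,
         corrected_bound = corr_count == 0,
         uncorrected_p = unc_count / n_perm,
         uncorrected_bound = unc_count == 0,
         n_perm = n_perm),
    class = "fwe_result"
  )
}

#' Searchlight permutation test with FWE correction
#'
#' Re-runs the whole searchlight under N label/score shuffles. Within one
#' permutation the same shuffled labels are used for every center (step
#' required by the max-statistic correction); uncorrected and
#' FWE-corrected p-values are derived from the per-center and
#' maximum-statistic null distributions respectively.
#'
#' @inheritParams run_searchlight
#' @param n_perm Number of permutations N.
#' @return An object of class `mvpa_searchlight_perm`: the observed
#'   `searchlight` result, `fwe` (an [fwe_correct()] result), and
#'   `permuted_maps`.
#' @export
permutation_test_searchlight <- function(data, labels, folds, radius = 4,
                                         model = make_model("svm"),
                                         preprocess = NULL, n_perm = 100L,
                                         seed = 1L, workers = 1L) {
  space <- feature_space(data)
  if (is.null(space))
    stop_mvpa("searchlight requires geometry: the feature space is tabular")
  spheres <- build_spheres(space, radius)
  observed <- run_searchlight(data, labels, folds, model = model,
                              preprocess = preprocess, seed = seed,
                              spheres = spheres, workers = workers)
  n <- nrow(data)
  one_perm <- function(i) {
    ys <- withr::with_seed(derive_seed(seed, i), labels[sample.int(n)])
    run_searchlight(data, ys, folds, model = model, preprocess = preprocess,
                    seed = derive_seed(seed, i), spheres = spheres,
                    workers = 1L)$statistic
  }
  idx <- seq_len(n_perm)
  maps <- if (workers > 1L) {
    do.call(rbind, parallel::mclapply(idx, one_perm, mc.cores = workers))
  } else {
    do.call(rbind, lapply(idx, one_perm))
  }
  structure(
    list(searchlight = observed, fwe = fwe_correct(observed$statistic, maps),
         permuted_maps = maps, n_perm = as.integer(n_perm), seed = seed),
    class = "mvpa_searchlight_perm"
  )
}
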