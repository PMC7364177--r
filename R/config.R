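# Run-configuration files: one structured YAML file describes a whole
# analysis (input, preprocessing, model, ROI/searchlight mode, statistics,
# outputs, optional fusion) and can be saved, reloaded and re-run
# bit-identically. Unknown keys are rejected rather than silently ignored.

.config_schema <- list(
  input = c("samples", "features", "mask", "labels", "task", "folds", "k"),
  preprocess = NULL, # list of steps, validated separately
  model = c("algorithm", "params"),
  mode = c("type", "radius"),
  statistics = c("n_perm", "fwe"),
  output = c("dir", "weight_maps", "roc", "predictions"),
  fusion = c("strategy", "blocks"),
  seed = NULL
)
.step_keys <- list(
  zscore = c("step", "direction"),
  pca = c("step", "variance", "n_components"),
  select = c("step", "method", "n", "fraction", "inner_folds", "lambda")
)
.block_keys <- c("name", "samples", "features", "mask", "normalize")

default_config <- function() {
  list(
    input = list(samples = NULL, features = NULL, mask = NULL, labels = NULL,
                 task = "classify", folds = NULL, k = 5L),
    preprocess = list(),
    model = list(algorithm = "svm", params = list()),
    mode = list(type = "roi", radius = 4),
    statistics = list(n_perm = 0L, fwe = FALSE),
    output = list(dir = "mvpa_results", weight_maps = TRUE, roc = TRUE,
                  predictions = TRUE),
    fusion = list(strategy = NULL, blocks = NULL),
    seed = 1L
  )
}

check_unknown <- function(x, allowed, where, problems) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0L)
    problems <- c(problems, paste0("unknown key(s) in ", where, ": ",
                                   paste(bad, collapse = ", ")))
  problems
}

#' Validate a run configuration
#'
#' Collects and returns *every* problem found (unknown keys, missing
#' required fields, invalid values), not just the first.
#'
#' @param config A configuration list (e.g. from [load_config()]).
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  problems <- check_unknown(config, names(.config_schema), "top level", problems)
  for (sec in intersect(names(config), names(.config_schema))) {
    allowed <- .config_schema[[sec]]
    if (!is.null(allowed) && is.list(config[[sec]]))
      problems <- check_unknown(config[[sec]], allowed, sec, problems)
  }
  inp <- config$input %||% list()
  fus <- config$fusion %||% list()
  fused <- !is.null(fus$strategy)
  if (fused) {
    if (!fus$strategy %in% c("concatenate", "vote"))
      problems <- c(problems, "fusion.strategy must be 'concatenate' or 'vote'")
    if (is.null(fus$blocks) || length(fus$blocks) < 1L) {
      problems <- c(problems, "fusion.strategy is set but fusion.blocks is empty")
    } else {
      for (i in seq_along(fus$blocks)) {
        b <- fus$blocks[[i]]
        problems <- check_unknown(b, .block_keys,
                                  paste0("fusion.blocks[", i, "]"), problems)
        if (is.null(b$samples) && is.null(b$features))
          problems <- c(problems, paste0("fusion.blocks[", i,
                                         "] needs samples or features"))
      }
    }
  } else if (is.null(inp$samples) && is.null(inp$features)) {
    problems <- c(problems, "input.samples or input.features is required")
  }
  if (!is.null(inp$samples) && is.null(inp$mask))
    problems <- c(problems, "input.mask is required with volumetric input.samples")
  if (is.null(inp$labels))
    problems <- c(problems, "input.labels is required")
  if (!is.null(inp$task) && !inp$task %in% c("classify", "regress"))
    problems <- c(problems, "input.task must be 'classify' or 'regress'")
  md <- config$mode %||% list()
  if (!is.null(md$type) && !md$type %in% c("roi", "searchlight"))
    problems <- c(problems, "mode.type must be 'roi' or 'searchlight'")
  for (i in seq_along(config$preprocess %||% list())) {
    st <- config$preprocess[[i]]
    nm <- st$step %||% "<missing>"
    if (!nm %in% names(.step_keys)) {
      problems <- c(problems, paste0("preprocess[", i, "]: unknown step '",
                                     nm, "'"))
    } else {
      problems <- check_unknown(st, .step_keys[[nm]],
                                paste0("preprocess[", i, "] (", nm, ")"),
                                problems)
    }
  }
  mod <- config$model %||% list()
  if (!is.null(mod$algorithm)) {
    task <- inp$task %||% "classify"
    tr <- tryCatch({
      do.call(make_model, c(list(algorithm = mod$algorithm, task = task),
                            mod$params %||% list()))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(tr)) problems <- c(problems, paste0("model: ", tr))
  }
  problems
}

merge_defaults <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) {
      user[nm] <- list(defaults[[nm]])
    } else if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
               !is.null(names(defaults[[nm]]))) {
      user[nm] <- list(merge_defaults(user[[nm]], defaults[[nm]]))
    }
  }
  user
}

#' Resolve a configuration: validate and materialize every default
#'
#' The returned config names every effective parameter explicitly,
#' including the model defaults (e.g. `c = 1`, `k = 11`, `n_trees = 500`,
#' PCA variance 0.95), so a saved resolved config is a complete record of
#' the analysis.
#'
#' @param config A configuration list.
#' @return The resolved configuration (class `mvpa_config`).
#' @export
resolve_config <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0L)
    stop_mvpa("invalid configuration:\n  - ",
              paste(problems, collapse = "\n  - "))
  config <- merge_defaults(config, default_config())
  task <- config$input$task
  spec <- do.call(make_model,
                  c(list(algorithm = config$model$algorithm, task = task),
                    config$model$params))
  config$model$params <- spec$params
  config$preprocess <- lapply(config$preprocess, function(st) {
    if (st$step == "zscore") st$direction <- st$direction %||% "columns"
    if (st$step == "pca" && is.null(st$n_components))
      st$variance <- st$variance %||% 0.95
    if (st$step == "select" && st$method %||% "" == "lasso")
      st$inner_folds <- st$inner_folds %||% 10L
    st
  })
  structure(config, class = "mvpa_config")
}

#' Load a run configuration from YAML
#'
#' Unknown keys (e.g. written by a newer version) raise an explicit error;
#' defaults are materialized so that `load_config(save_config(x)) = x`.
#'
#' @param path Path to a YAML configuration file.
#' @return A resolved `mvpa_config`.
#' @export
load_config <- function(path) {
  resolve_config(yaml::read_yaml(path))
}

#' Save a run configuration as YAML
#'
#' @param config A configuration list or `mvpa_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (!inherits(config, "mvpa_config")) config <- resolve_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

load_config_input <- function(inp) {
  if (!is.null(inp$samples)) {
    data <- load_samples(inp$samples, inp$mask)
  } else {
    data <- load_table(inp$features, "features")
    if (!is.null(inp$mask)) {
      keep <- which(as.numeric(load_table(inp$mask, "scores")) != 0)
      data <- set_space(data[, keep, drop = FALSE], NULL)
    }
  }
  data
}

build_steps <- function(pp, amount_override = NULL) {
  lapply(pp, function(st) {
    switch(st$step,
      zscore = step_zscore(st$direction),
      pca = step_pca(var_threshold = st$variance %||% 0.95,
                     n_components = st$n_components),
      select = {
        n <- st$n; fr <- st$fraction
        if (!is.null(amount_override)) {
          if (amount_override$type == "n") { n <- amount_override$value; fr <- NULL }
          else { fr <- amount_override$value; n <- NULL }
        }
        step_select(method = st$method, n = n, fraction = fr,
                    inner_folds = st$inner_folds %||% 10L,
                    lambda = st$lambda)
      }
    )
  })
}

# A selection step may list several amounts; each fans out into an
# independent analysis (reported together with the Bonferroni-adjusted
# alpha, never just the best).
select_amounts <- function(pp) {
  for (st in pp) {
    if (identical(st$step, "select")) {
      if (length(st$n %||% numeric()) > 1L)
        return(lapply(st$n, function(v) list(type = "n", value = v)))
      if (length(st$fraction %||% numeric()) > 1L)
        return(lapply(st$fraction, function(v) list(type = "fraction", value = v)))
    }
  }
  NULL
}

#' Execute a configured analysis and write its result bundle
#'
#' Runs the configured pipeline (ROI or searchlight, with optional
#' permutation statistics and fusion) and writes metrics, per-fold results,
#' predictions, ROC points, weight maps, p-values, the fully resolved
#' configuration and a log with all seeds to the output directory. When a
#' selection step lists several amounts, each amount becomes an independent
#' sub-run and the joint report annotates the Bonferroni-adjusted alpha.
#'
#' @param config An `mvpa_config`, raw configuration list, or YAML path.
#' @param dir Optional output-directory override.
#' @return Named list of result objects, invisibly.
#' @export
run_config <- function(config, dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "mvpa_config")) config <- resolve_config(config)
  dir <- dir %||% config$output$dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  task <- config$input$task
  spec <- do.call(make_model,
                  c(list(algorithm = config$model$algorithm, task = task),
                    config$model$params))
  labels <- load_table(config$input$labels,
                       if (task == "classify") "labels" else "scores")
  fused <- !is.null(config$fusion$strategy)
  if (fused) {
    blocks <- lapply(config$fusion$blocks, function(b) {
      feature_block(b$name %||% "block",
                    load_config_input(b),
                    normalize = b$normalize %||% "none")
    })
    data <- blocks[[1]]$data
  } else {
    data <- load_config_input(config$input)
  }
  n <- nrow(data)
  folds <- if (!is.null(config$input$folds)) {
    load_table(config$input$folds, "folds")
  } else {
    random_folds(n, config$input$k, labels = if (task == "classify") labels,
                 seed = derive_seed(seed, 7L))
  }
  amounts <- select_amounts(config$preprocess)
  runs <- if (is.null(amounts)) list(NULL) else amounts
  results <- list()
  metrics_rows <- list()
  for (ri in seq_along(runs)) {
    steps <- build_steps(config$preprocess, runs[[ri]])
    if (length(steps) == 0L) steps <- NULL
    tag <- if (is.null(runs[[ri]])) "run" else
      paste0("run_", runs[[ri]]$type, "_", runs[[ri]]$value)
    if (config$mode$type == "searchlight") {
      if (config$statistics$n_perm > 0L) {
        sl <- permutation_test_searchlight(
          data, labels, folds, radius = config$mode$radius, model = spec,
          preprocess = steps, n_perm = config$statistics$n_perm, seed = seed)
        res <- sl$searchlight
        write_map(sl$fwe$uncorrected_p, res$space,
                  file.path(dir, paste0(tag, "_p_uncorrected.nii")))
        if (isTRUE(config$statistics$fwe))
          write_map(sl$fwe$corrected_p, res$space,
                    file.path(dir, paste0(tag, "_p_fwe.nii")))
        utils::write.csv(
          data.frame(permutation = seq_len(sl$n_perm), max_statistic = sl$fwe$max_null),
          file.path(dir, paste0(tag, "_null_max.csv")), row.names = FALSE)
        results[[tag]] <- sl
      } else {
        res <- run_searchlight(data, labels, folds,
                               radius = config$mode$radius, model = spec,
                               preprocess = steps, seed = seed)
        results[[tag]] <- res
      }
      write_map(res$statistic, res$space,
                file.path(dir, paste0(tag, "_statistic.nii")))
      write_map(res$n_voxels, res$space,
                file.path(dir, paste0(tag, "_sphere_size.nii")))
      metrics_rows[[ri]] <- tibble::tibble(
        run = tag, statistic_mean = mean(res$statistic),
        statistic_max = max(res$statistic))
    } else {
      res <- if (fused) {
        run_fusion(blocks, labels, folds, strategy = config$fusion$strategy,
                   model = spec, preprocess = steps, seed = seed)
      } else {
        run_cv(data, labels, folds, model = spec, preprocess = steps,
               seed = seed)
      }
      results[[tag]] <- res
      row <- cbind(tibble::tibble(run = tag), glance(res))
      if (config$statistics$n_perm > 0L && !fused) {
        pt <- permutation_test(data, labels, folds, model = spec,
                               preprocess = steps,
                               n_perm = config$statistics$n_perm, seed = seed)
        results[[paste0(tag, "_perm")]] <- pt
        row$p_value <- pt$p$p
        row$p_report <- format(pt$p)
        utils::write.csv(tidy(pt), file.path(dir, paste0(tag, "_null.csv")),
                         row.names = FALSE)
      }
      metrics_rows[[ri]] <- row
      if (!is.null(res$per_fold))
        utils::write.csv(res$per_fold, file.path(dir, paste0(tag, "_per_fold.csv")),
                         row.names = FALSE)
      if (isTRUE(config$output$predictions))
        utils::write.csv(res$predictions,
                         file.path(dir, paste0(tag, "_predictions.csv")),
                         row.names = FALSE)
      if (isTRUE(config$output$roc) && task == "classify" && !is.null(res$roc))
        utils::write.csv(res$roc$curve, file.path(dir, paste0(tag, "_roc.csv")),
                         row.names = FALSE)
      if (isTRUE(config$output$weight_maps) && !is.null(res$weights)) {
        utils::write.csv(
          data.frame(feature = seq_along(res$weights$mean),
                     mean_weight = res$weights$mean),
          file.path(dir, paste0(tag, "_weights_mean.csv")), row.names = FALSE)
        if (!is.null(feature_space(data)))
          write_map(res$weights$mean, feature_space(data),
                    file.path(dir, paste0(tag, "_weights_mean.nii")))
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics_rows)
  if (length(runs) > 1L) {
    metrics$n_comparisons <- length(runs)
    metrics$alpha_bonferroni <- 0.05 / length(runs)
  }
  utils::write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  save_config(config, file.path(dir, "resolved_config.yaml"))
  writeLines(c(
    sprintf("mvpakit %s | R %s", as.character(utils::packageVersion("mvpakit")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", seed),
    sprintf("fold seed: %d", derive_seed(seed, 7L)),
    sprintf("runs: %s", paste(names(results), collapse = ", "))
  ), file.path(dir, "log.txt"))
  invisible(results)
}
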