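#' Specification for a synthetic volumetric dataset
#'
#' Describes a synthetic study: a voxel grid, a mask, a signal region, and
#' either a two-class mean-shift (classification) or a score-coupled voxel
#' response (regression). Defaults emulate a small decoding study: an
#' 8x8x8 grid with an inscribed spherical mask (brain-mask-like geometry,
#' 179 voxels), 20 samples per class, a centered 3x3x3 signal box, and a
#' mean shift of 5 noise-SDs between classes.
#'
#' @param grid Length-3 voxel grid dimensions.
#' @param n_per_class Samples per class (classification).
#' @param n_subjects Number of subjects (regression).
#' @param signal_region 2x3 matrix of voxel-coordinate bounds
#'   `rbind(lower, upper)` for the signal box, or `NULL` for a centered
#'   3x3x3 box.
#' @param effect Class mean shift inside the signal region, in units of
#'   `noise_sd` (classification).
#' @param noise_sd Standard deviation of the i.i.d. Gaussian voxel noise.
#' @param task `"classify"` or `"regress"`.
#' @param regression_slope Voxel response per unit score inside the signal
#'   region (regression).
#' @param score_range Uniform range the regression scores are drawn from
#'   (seconds; reaction-time-like).
#' @param smooth_fwhm Isotropic Gaussian smoothing of each sample volume,
#'   as a full width at half maximum in voxels (0 = off). Adds spatial
#'   autocorrelation to the otherwise i.i.d. noise.
#' @param mask `"sphere"` (inscribed sphere) or `"full"` (whole grid).
#' @param folds Number of stratified cross-validation folds to assign.
#' @param seed Integer seed; together with the spec it fully determines the
#'   generated data (byte-identical files on re-run).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(grid = c(8L, 8L, 8L),
                         n_per_class = 20L,
                         n_subjects = 20L,
                         signal_region = NULL,
                         effect = 5,
                         noise_sd = 1,
                         task = c("classify", "regress"),
                         regression_slope = 1,
                         score_range = c(0.3, 0.9),
                         smooth_fwhm = 0,
                         mask = c("sphere", "full"),
                         folds = 5L,
                         seed = 1L) {
  task <- match.arg(task)
  mask <- match.arg(mask)
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 3L))
    stop_mvpa("grid must be three dimensions of at least 3 voxels")
  if (noise_sd <= 0) stop_mvpa("noise_sd must be > 0")
  if (is.null(signal_region)) {
    c0 <- pmax(1L, as.integer(floor(grid / 2)))
    signal_region <- rbind(c0, pmin(grid, c0 + 2L))
  }
  signal_region <- matrix(as.integer(signal_region), nrow = 2L)
  if (any(signal_region[1, ] < 1L) || any(signal_region[2, ] > grid) ||
      any(signal_region[1, ] > signal_region[2, ]))
    stop_mvpa("signal_region must be a non-empty box inside the grid")
  n <- if (task == "classify") 2L * as.integer(n_per_class) else as.integer(n_subjects)
  if (n < 4L) stop_mvpa("need at least 4 samples")
  structure(
    list(grid = grid, n_per_class = as.integer(n_per_class),
         n_subjects = as.integer(n_subjects), signal_region = signal_region,
         effect = effect, noise_sd = noise_sd, task = task,
         regression_slope = regression_slope, score_range = score_range,
         smooth_fwhm = smooth_fwhm, mask = mask,
         folds = as.integer(folds), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

fixture_space <- function(spec) {
  arr <- array(1, dim = spec$grid)
  if (spec$mask == "sphere") {
    ctr <- (spec$grid + 1) / 2
    r <- (min(spec$grid) - 1) / 2
    idx <- arrayInd(seq_along(arr), spec$grid)
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
    arr[d2 > r^2] <- 0
  }
  volume_space(arr)
}

# Separable Gaussian smoothing with edge renormalization (kernel mass
# falling outside the volume is redistributed, so means are preserved).
gauss_smooth3d <- function(arr, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    wt <- array(0, d)
    for (j in seq_along(k)) {
      o <- j - r - 1L
      src <- seq.int(max(1L, 1L + o), min(d[ax], d[ax] + o))
      tgt <- src - o
      it <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      is <- it
      it[[ax]] <- tgt
      is[[ax]] <- src
      out[it[[1]], it[[2]], it[[3]]] <-
        out[it[[1]], it[[2]], it[[3]]] + k[j] * arr[is[[1]], is[[2]], is[[3]]]
      wt[it[[1]], it[[2]], it[[3]]] <- wt[it[[1]], it[[2]], it[[3]]] + k[j]
    }
    arr <- out / wt
  }
  arr
}

# Smooth each sample's volume (zero outside the mask) and re-extract the
# in-mask columns.
smooth_samples <- function(x, space, fwhm) {
  d <- space$dims
  t(apply(x, 1L, function(v) {
    arr <- array(0, d)
    arr[space$mask_linear] <- v
    gauss_smooth3d(arr, fwhm)[space$mask_linear]
  }))
}

signal_columns <- function(space, box) {
  co <- space$coords
  which(co[, 1] >= box[1, 1] & co[, 1] <= box[2, 1] &
        co[, 2] >= box[1, 2] & co[, 2] <= box[2, 2] &
        co[, 3] >= box[1, 3] & co[, 3] <= box[2, 3])
}

#' Generate a synthetic two-class volume set
#'
#' Voxels are i.i.d. Gaussian noise; class +1 samples get an additional mean
#' shift of `effect * noise_sd` inside the signal region. Classes are
#' balanced and stratified folds are assigned. With `dir` given, the set is
#' written to disk in the same formats [load_samples()] and [load_table()]
#' consume (uncompressed per-sample .nii volumes, mask.nii, labels.txt,
#' folds.txt, and a manifest.yaml recording the spec and seed).
#'
#' @param spec A [fixture_spec()] with `task = "classify"`.
#' @param dir Optional output directory; created if needed.
#' @return A list with `data` (n x features matrix, geometry attached),
#'   `labels` (+1/-1), `folds`, `space`, `signal_columns`, `spec`, and — when
#'   written — `paths`.
#' @export
make_classification_volumes <- function(spec = fixture_spec(), dir = NULL) {
  if (spec$task != "classify") stop_mvpa("spec task is not 'classify'")
  space <- fixture_space(spec)
  p <- n_features(space)
  n <- 2L * spec$n_per_class
  labels <- rep(c(1, -1), each = spec$n_per_class)
  sig <- signal_columns(space, spec$signal_region)
  data <- withr::with_seed(spec$seed, {
    x <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), nrow = n)
    x[labels == 1, sig] <- x[labels == 1, sig] + spec$effect * spec$noise_sd
    x
  })
  if (spec$smooth_fwhm > 0)
    data <- smooth_samples(data, space, spec$smooth_fwhm)
  folds <- random_folds(n, spec$folds, labels = labels,
                        seed = derive_seed(spec$seed, 9901L))
  out <- list(data = set_space(data, space), labels = labels, folds = folds,
              space = space, signal_columns = sig, spec = spec)
  if (!is.null(dir)) out$paths <- write_fixture_set(out, dir)
  out
}

#' Generate a synthetic regression volume set
#'
#' Each subject gets a score drawn from `Uniform(score_range)`; voxels in the
#' signal region respond as `regression_slope * score` plus Gaussian noise,
#' voxels elsewhere are pure noise.
#'
#' @inheritParams make_classification_volumes
#' @param spec A [fixture_spec()] with `task = "regress"`.
#' @return As [make_classification_volumes()], with `scores` in place of
#'   `labels`.
#' @export
make_regression_volumes <- function(spec, dir = NULL) {
  if (spec$task != "regress") stop_mvpa("spec task is not 'regress'")
  space <- fixture_space(spec)
  p <- n_features(space)
  n <- spec$n_subjects
  sig <- signal_columns(space, spec$signal_region)
  gen <- withr::with_seed(spec$seed, {
    scores <- stats::runif(n, spec$score_range[1], spec$score_range[2])
    x <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), nrow = n)
    x[, sig] <- x[, sig] + spec$regression_slope * scores
    list(scores = scores, x = x)
  })
  if (spec$smooth_fwhm > 0)
    gen$x <- smooth_samples(gen$x, space, spec$smooth_fwhm)
  folds <- random_folds(n, spec$folds, seed = derive_seed(spec$seed, 9902L))
  out <- list(data = set_space(gen$x, space), scores = gen$scores,
              folds = folds, space = space, signal_columns = sig, spec = spec)
  if (!is.null(dir)) out$paths <- write_fixture_set(out, dir)
  out
}

write_fixture_set <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(fix$data)
  sample_paths <- file.path(dir, sprintf("sample_%03d.nii", seq_len(n)))
  for (i in seq_len(n)) write_map(fix$data[i, ], fix$space, sample_paths[i])
  mask_path <- file.path(dir, "mask.nii")
  write_map(rep(1, n_features(fix$space)), fix$space, mask_path)
  label_path <- file.path(dir, if (fix$spec$task == "classify") "labels.txt" else "scores.txt")
  y <- if (fix$spec$task == "classify") fix$labels else fix$scores
  writeLines(format(y, digits = 17, trim = TRUE, scientific = FALSE), label_path)
  fold_path <- file.path(dir, "folds.txt")
  writeLines(as.character(fix$folds), fold_path)
  manifest <- file.path(dir, "manifest.yaml")
  sp <- fix$spec
  sp$signal_region <- as.integer(sp$signal_region)
  yaml::write_yaml(unclass(sp), manifest)
  list(samples = sample_paths, mask = mask_path, labels = label_path,
       folds = fold_path, manifest = manifest)
}
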