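#' Enumerate searchlight sphere membership for every in-mask voxel
#'
#' The sphere is the closed ball of lattice points: all integer offsets `d`
#' with `||d||^2 <= radius^2` (radius in voxel units; radius 0 gives the
#' center alone, radius 1 the center plus its 6 face neighbors). Each
#' center's member list is the sphere intersected with the mask, as column
#' indices in canonical order; centers iterate in canonical column order.
#'
#' @param space A [volume_space()].
#' @param radius Sphere radius in voxel-index units (>= 0). Set
#'   `mm = TRUE` to interpret it in millimeters instead, scaling each axis
#'   by the voxel size.
#' @param mm Interpret `radius` in millimeters (default FALSE).
#' @return An object of class `sphere_index`: `radius`, `offsets`
#'   (m x 3 integer matrix), `members` (list of column-index vectors, one
#'   per center), `n_voxels` (sphere sizes), `space`.
#' @export
build_spheres <- function(space, radius, mm = FALSE) {
  if (radius < 0) stop_mvpa("radius must be >= 0")
  vs <- if (mm) space$voxel_size else c(1, 1, 1)
  rng <- lapply(1:3, function(a) {
    m <- floor(radius / vs[a])
    seq.int(-m, m)
  })
  g <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  d2 <- (g[, 1] * vs[1])^2 + (g[, 2] * vs[2])^2 + (g[, 3] * vs[3])^2
  offsets <- g[d2 <= radius^2 + 1e-9, , drop = FALSE]
  lut <- array(0L, dim = space$dims)
  lut[space$mask_linear] <- seq_len(n_features(space))
  dims <- space$dims
  members <- vector("list", n_features(space))
  for (j in seq_len(n_features(space))) {
    ctr <- space$coords[j, ]
    pts <- sweep(offsets, 2L, ctr, "+")
    ok <- pts[, 1] >= 1L & pts[, 1] <= dims[1] &
          pts[, 2] >= 1L & pts[, 2] <= dims[2] &
          pts[, 3] >= 1L & pts[, 3] <= dims[3]
    cols <- lut[pts[ok, , drop = FALSE]]
    members[[j]] <- sort(cols[cols > 0L])
  }
  structure(
    list(radius = radius, offsets = offsets, members = members,
         n_voxels = lengths(members), space = space),
    class = "sphere_index"
  )
}

#' Voxel-wise searchlight analysis
#'
#' Runs the full cross-validated pipeline restricted to each center's
#' sphere, assigning every in-mask voxel the aggregate statistic (pooled
#' classification accuracy, or prediction precision r for regression).
#' Preprocessing defaults to none inside the searchlight but the same
#' pipeline hooks are honored. Per-center randomness is derived from
#' `(seed, center)`, so the map is identical regardless of execution order
#' or worker count.
#'
#' @inheritParams run_cv
#' @param radius Sphere radius in voxel units (see [build_spheres()]).
#' @param spheres Optional precomputed [build_spheres()] index (reused by
#'   the permutation engine).
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return An object of class `mvpa_searchlight`: `statistic` (per-center),
#'   `n_voxels`, `space`, `radius`, `task`.
#' @export
run_searchlight <- function(data, labels, folds, radius = 4,
                            model = make_model("svm"), preprocess = NULL,
                            seed = 1L, spheres = NULL, workers = 1L) {
  space <- feature_space(data)
  if (is.null(space))
    stop_mvpa("searchlight requires geometry: the feature space is tabular")
  if (is.null(spheres)) spheres <- build_spheres(space, radius)
  folds <- validate_folds(folds)
  data <- as.matrix(data)
  one_center <- function(j) {
    eng <- cv_engine(data[, spheres$members[[j]], drop = FALSE], labels,
                     folds, model, preprocess,
                     seed = derive_seed(seed, j), light = TRUE)
    pooled_statistic(eng)
  }
  idx <- seq_along(spheres$members)
  stat <- if (workers > 1L) {
    unlist(parallel::mclapply(idx, one_center, mc.cores = workers))
  } else {
    vapply(idx, one_center, numeric(1))
  }
  structure(
    list(statistic = stat, n_voxels = spheres$n_voxels, space = space,
         radius = spheres$radius, task = model$task, seed = seed),
    class = "mvpa_searchlight"
  )
}

#' @export
print.mvpa_searchlight <- function(x, ...) {
  cat(sprintf(
    "<mvpa_searchlight> radius %g, %d centers; statistic (%s): mean %.3f, max %.3f\n",
    x$radius, length(x$statistic),
    if (x$task == "classify") "accuracy" else "r",
    mean(x$statistic), max(x$statistic)
  ))
  invisible(x)
}
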