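#' Voxel-grid geometry of a volumetric feature space
#'
#' A `volume_space` records how the columns of a samples-by-features matrix
#' map back into a 3-D voxel grid: grid dimensions, voxel sizes, the
#' voxel-to-world affine, and the ordered in-mask voxel coordinates (one per
#' feature column). The canonical column order is ascending linear voxel
#' index with the x axis varying fastest, which coincides with R's native
#' column-major array order; it is a pure function of the mask and never of
#' sample content.
#'
#' @param mask A 3-D array (numeric or logical); nonzero voxels are in-mask.
#' @param voxel_size Length-3 voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform. Defaults to a scaled identity
#'   built from `voxel_size`.
#' @param reference Optional NIfTI image (as read by [RNifti::readNifti()])
#'   whose header is reused when writing result maps.
#' @return An object of class `volume_space`.
#' @seealso [load_samples()], [write_map()]
#' @export
volume_space <- function(mask, voxel_size = c(1, 1, 1), affine = NULL,
                         reference = NULL) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop_mvpa("mask must be a 3-D array, got ", length(dim(mask)), " dimensions")
  dims <- dim(mask)
  inmask <- is.finite(mask) & mask != 0
  mask_linear <- which(inmask)
  if (length(mask_linear) == 0L) stop_mvpa("empty mask: no nonzero voxels")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop_mvpa("affine must be a 4x4 matrix")
  structure(
    list(
      dims = as.integer(dims),
      voxel_size = as.numeric(voxel_size),
      affine = affine,
      mask = inmask,
      mask_linear = as.integer(mask_linear),
      coords = arrayInd(mask_linear, dims),
      reference = reference
    ),
    class = "volume_space"
  )
}

#' @export
print.volume_space <- function(x, ...) {
  cat(sprintf(
    "<volume_space> %s grid, %.3gx%.3gx%.3g mm voxels, %d in-mask voxels\n",
    paste(x$dims, collapse = "x"),
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    n_features(x)
  ))
  invisible(x)
}

#' Number of in-mask voxels (feature columns) of a space
#' @param space A `volume_space`.
#' @return Integer count.
#' @export
n_features <- function(space) length(space$mask_linear)

same_geometry <- function(a, b, tol = 1e-4) {
  identical(as.integer(a$dims), as.integer(b$dims)) &&
    max(abs(a$affine - b$affine)) <= tol
}

# Attach/retrieve the feature space carried by a samples-by-features matrix.
# A NULL space means tabular data with no geometry.
set_space <- function(x, space) {
  attr(x, "space") <- space
  x
}

#' Feature space attached to a feature matrix
#' @param x A matrix returned by [load_samples()] or a fixture generator.
#' @return A `volume_space`, or `NULL` for tabular (no-geometry) data.
#' @export
feature_space <- function(x) attr(x, "space", exact = TRUE)
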