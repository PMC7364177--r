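#' Read a binary mask into a volume space
#'
#' Nonzero voxels are treated as in-mask (files produced by other tools often
#' contain near-1 floating values rather than exact ones).
#'
#' @param path Path to a NIfTI file (.nii or .nii.gz).
#' @return A [volume_space()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop_mvpa("mask '", path, "' is not a 3-D volume")
  volume_space(
    arr,
    voxel_size = RNifti::pixdim(img)[seq_len(3)],
    affine = unclass(RNifti::xform(img)),
    reference = img
  )
}

#' Load per-sample NIfTI volumes into a feature matrix
#'
#' Each file contributes one row; columns are the in-mask voxels of `mask`
#' in canonical order (ascending linear voxel index, x fastest). Row order
#' equals the order of `paths` — the caller controls it (e.g. alphabetical
#' file order).
#'
#' @param paths Character vector of NIfTI file paths, one sample each.
#' @param mask Mask source: a file path, a [volume_space()], or a 3-D array.
#' @return A numeric matrix `[n_samples x n_in-mask_voxels]` with the
#'   geometry attached (retrievable via [feature_space()]); row names are the
#'   file base names.
#' @export
load_samples <- function(paths, mask) {
  if (length(paths) < 1L) stop_mvpa("no sample files given")
  space <- if (inherits(mask, "volume_space")) mask
           else if (is.character(mask)) read_mask(mask)
           else volume_space(mask)
  out <- matrix(NA_real_, nrow = length(paths), ncol = n_features(space))
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
      stop_mvpa("sample '", paths[i], "' is not a 3-D volume")
    ispace <- volume_space(array(1, dim(arr)),
                           voxel_size = RNifti::pixdim(img)[seq_len(3)],
                           affine = unclass(RNifti::xform(img)))
    if (!same_geometry(ispace, space))
      stop_mvpa("geometry mismatch: '", paths[i],
                "' does not share the mask's dimensions/affine (tolerance 1e-4)")
    v <- arr[space$mask_linear]
    if (any(!is.finite(v)))
      stop_mvpa("non-finite values (NaN/Inf) inside the mask in '", paths[i],
                "'; clean or re-mask the data (values are never imputed)")
    out[i, ] <- v
  }
  rownames(out) <- basename(paths)
  set_space(out, space)
}

#' Canonicalize two-class labels to +1/-1
#'
#' Accepts the +1/-1 coding directly or the 1/0 alias (0 becomes -1). Any
#' other coding, or more than two classes, is rejected: only two-way
#' classification is supported.
#'
#' @param x Numeric vector of raw labels.
#' @return Numeric vector in \{+1, -1\}.
#' @export
canonical_labels <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_mvpa("labels contain non-finite values")
  u <- sort(unique(x))
  if (length(u) > 2L)
    stop_mvpa("found ", length(u),
              " distinct label values; only two-way classification is supported")
  if (length(u) < 2L) stop_mvpa("labels contain a single class")
  if (identical(u, c(-1, 1))) return(x)
  if (identical(u, c(0, 1))) return(ifelse(x == 0, -1, 1))
  stop_mvpa("unsupported label coding {", paste(u, collapse = ", "),
            "}; use +1/-1 or 1/0")
}

validate_folds <- function(fold) {
  fold <- as.numeric(fold)
  if (any(!is.finite(fold)) || any(fold != floor(fold)) || any(fold < 1))
    stop_mvpa("fold assignments must be positive integers")
  fold <- as.integer(fold)
  k <- max(fold)
  if (k < 2L) stop_mvpa("need at least 2 folds, got K=", k)
  missing <- setdiff(seq_len(k), unique(fold))
  if (length(missing) > 0L)
    stop_mvpa("empty fold index: fold(s) ", paste(missing, collapse = ", "),
              " have no samples (folds must be contiguous 1..K)")
  fold
}

#' Load a delimited table as labels, folds, or a feature matrix
#'
#' Plain numeric text/CSV/TSV without header. Labels and folds must be a
#' single column (one row per sample). Feature tables are read as
#' samples-by-features matrices with no geometry attached.
#'
#' @param path Path to the delimited file.
#' @param expected One of `"labels"`, `"scores"`, `"folds"`, `"features"`.
#' @return Canonical labels (+1/-1), numeric scores, validated integer fold
#'   vector, or a numeric matrix.
#' @export
load_table <- function(path, expected = c("labels", "scores", "folds", "features")) {
  expected <- match.arg(expected)
  dt <- data.table::fread(path, header = FALSE)
  m <- as.matrix(dt)
  if (!is.numeric(m)) stop_mvpa("'", path, "' contains non-numeric content")
  if (expected == "features") {
    if (any(!is.finite(m)))
      stop_mvpa("non-finite values in feature table '", path, "'")
    return(set_space(unname(m), NULL))
  }
  if (ncol(m) != 1L)
    stop_mvpa("'", path, "' must be a single column for ", expected,
              ", got ", ncol(m), " columns")
  v <- as.numeric(m[, 1L])
  switch(expected,
    labels = canonical_labels(v),
    scores = {
      if (any(!is.finite(v))) stop_mvpa("scores contain non-finite values")
      v
    },
    folds = validate_folds(v)
  )
}

#' Write a per-feature vector back into brain space as a NIfTI map
#'
#' In-mask voxels carry `values` in canonical column order; all out-of-mask
#' voxels are 0. The header (dimensions, voxel sizes, affine) is copied from
#' the space's reference image when available.
#'
#' @param values Numeric vector, one value per in-mask voxel.
#' @param space A [volume_space()]; tabular (NULL) spaces cannot be written.
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_map <- function(values, space, path) {
  if (is.null(space) || !inherits(space, "volume_space"))
    stop_mvpa("no geometry to write: the feature space is tabular")
  if (length(values) != n_features(space))
    stop_mvpa("length(values) = ", length(values), " but the space has ",
              n_features(space), " in-mask voxels")
  arr <- array(0, dim = space$dims)
  arr[space$mask_linear] <- as.numeric(values)
  img <- if (!is.null(space$reference)) {
    RNifti::asNifti(arr, reference = space$reference)
  } else {
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- space$voxel_size
    RNifti::qform(im) <- structure(space$affine, code = 2L)
    im
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
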