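# Shared fixture builders. Everything is generated in code at test time;
# volume sets are written to tempdirs through RNifti directly so that I/O
# tests stay independent of the package's own writer.

# n small 3-D volumes + a mask with `n_mask` randomly chosen voxels,
# written as uncompressed NIfTI files. Returns the raw arrays for
# brute-force comparisons.
tiny_volume_files <- function(dir, n = 5, dims = c(8, 8, 8), n_mask = 100,
                              seed = 42) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(seed, {
    mask_arr <- array(0, dims)
    mask_arr[sample.int(prod(dims), n_mask)] <- 1
    arrays <- lapply(seq_len(n), function(i) array(rnorm(prod(dims)), dims))
    paths <- file.path(dir, sprintf("vol_%02d.nii", seq_len(n)))
    for (i in seq_len(n)) RNifti::writeNifti(RNifti::asNifti(arrays[[i]]), paths[i])
    mask_path <- file.path(dir, "mask.nii")
    RNifti::writeNifti(RNifti::asNifti(mask_arr), mask_path)
    list(paths = paths, mask_path = mask_path, arrays = arrays,
         mask_arr = mask_arr, dims = dims)
  })
}

# Two-class Gaussian matrix data with a mean shift `d` on the first
# `n_signal` features (no geometry; for fast model/CV tests).
sep_matrix_data <- function(n_per_class = 20, p = 10, d = 5, n_signal = 1,
                            seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * p), ncol = p)
    labels <- rep(c(1, -1), each = n_per_class)
    x[labels == 1, seq_len(n_signal)] <- x[labels == 1, seq_len(n_signal)] + d
    list(x = x, labels = labels)
  })
}

expect_mvpa_error <- function(expr, pattern) {
  expect_error(expr, pattern, class = "mvpakit_error")
}
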