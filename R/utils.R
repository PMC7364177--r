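# Internal helpers shared across modules.

#' Derive a child seed from a master seed and an index
#'
#' All randomness in the package flows through seeds derived as a pure
#' function of `(seed, i)`, so results are independent of execution order
#' and worker count. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed Master integer seed.
#' @param i Non-negative integer index (fold, permutation, sphere center, ...).
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  # affine congruential mix; operands stay < 2^53 so doubles are exact
  v <- (abs(as.numeric(seed)) %% 2147483647) * 69069 + as.numeric(i) * 104729 + 1
  as.integer(v %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mvpa <- function(..., class = "mvpakit_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# population (divide-by-n) standard deviation, per column
colsd_pop <- function(x) {
  m <- colMeans(x)
  sqrt(colMeans(sweep(x, 2L, m)^2))
}
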