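# Shared helpers.

#' Derive a bounded sub-seed from a master seed
#'
#' Deterministic mixing that keeps results inside the 32-bit integer range,
#' so one user-facing seed can drive many independent RNG streams.
#'
#' @param seed Master seed (integer).
#' @param ... Integer stream labels mixed into the result.
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) * 1103 + 12345) %% 2147483647
  }
  as.integer(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Block-mean downsampling of a matrix by an integer factor.
downsample_mean <- function(img, factor) {
  if (factor == 1) return(img)
  h <- nrow(img); w <- ncol(img)
  stopifnot(h %% factor == 0, w %% factor == 0)
  dim(img) <- c(factor, h %/% factor, factor, w %/% factor)
  colMeans(aperm(img, c(1, 3, 2, 4)), dims = 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
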