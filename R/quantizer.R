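#' Min-max quantizer for real-valued feature vectors
#'
#' Maps real-valued vectors (encoder-output surrogates) to discrete feature
#' functions with `n_levels` levels per dimension, and back. Quantization is
#' linear per dimension between fitted minimum and maximum, with values
#' outside the fitted range clipped to the boundary level; dequantization
#' returns bin centres, so the round-trip error is at most half a bin per
#' dimension and `quantize(dequantize(f)) == f` for every total `f`.
#'
#' @param x numeric matrix of reference vectors, one row per observation
#'   (at least 2 rows).
#' @param n_levels number of quantization levels `m`.
#' @return an object of class `quantizer` with per-dimension bounds
#'   `lo < hi` (degenerate dimensions are widened by a small epsilon).
#' @export
quantizer_fit <- function(x, n_levels) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_weam("quantizer_fit needs at least 2 vectors")
  if (!all(is.finite(x))) stop_weam("reference vectors must be finite")
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop_weam("n_levels must be >= 1")
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  deg <- hi <= lo
  if (any(deg)) {
    eps <- pmax(abs(lo[deg]) * 1e-6, 1e-6)
    lo[deg] <- lo[deg] - eps
    hi[deg] <- hi[deg] + eps
  }
  structure(list(n_dims = ncol(x), n_levels = n_levels, lo = lo, hi = hi),
            class = "quantizer")
}

#' @rdname quantizer_fit
#' @param q a fitted `quantizer`.
#' @param v numeric vector of length `n_dims`.
#' @return `quantize()`: a total `feature_function`.
#' @export
quantize <- function(q, v) {
  if (length(v) != q$n_dims)
    stop_weam("vector has ", length(v), " dims, quantizer expects ", q$n_dims)
  if (!all(is.finite(v))) stop_weam("cannot quantize non-finite values")
  lev <- floor((v - q$lo) / (q$hi - q$lo) * q$n_levels)
  lev <- pmin(pmax(lev, 0), q$n_levels - 1L)
  feature_function(lev, q$n_levels)
}

#' @rdname quantizer_fit
#' @param f a total `feature_function` with `n_levels` matching `q`.
#' @return `dequantize()`: the bin-centre numeric vector.
#' @export
dequantize <- function(q, f) {
  if (!inherits(f, "feature_function") || f$n_levels != q$n_levels ||
      ff_n_args(f) != q$n_dims)
    stop_weam("feature function does not match the quantizer's dimensions")
  if (!ff_is_total(f))
    stop_weam("dequantize requires a total function; fill undefined ",
              "arguments first")
  q$lo + (f$levels + 0.5) * (q$hi - q$lo) / q$n_levels
}
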