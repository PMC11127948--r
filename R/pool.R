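#' Pooling window specification
#'
#' @param window Positive integer window extents, either a single value
#'   applied to all three spatial axes or a length-3 vector `(k_d, k_h, k_w)`.
#'   The two-spatial-axis form of hybrid pooling is the `k_d = 1` special
#'   case.
#' @param stride Positive integer step size shared by all axes. Defaults to
#'   the first window extent (non-overlapping tiling).
#' @return A `pool_spec` object.
#' @export
pool_spec <- function(window, stride = window[1]) {
  window <- check_positive_int(window, "window")
  if (length(window) == 1L) window <- rep(window, 3L)
  if (length(window) != 3L) abort("`window` must have length 1 or 3")
  stride <- check_positive_int(stride, "stride")
  if (length(stride) != 1L) abort("`stride` must be a single integer")
  structure(list(window = window, stride = stride), class = "pool_spec")
}

as_pool_spec <- function(spec) {
  if (inherits(spec, "pool_spec")) spec else pool_spec(spec)
}

check_pool <- function(xdim, spec, pad) {
  ext <- xdim[3:5]
  if (length(pad) != 1L || pad < 0L) abort("`pad` must be a single nonnegative integer")
  if (any(2L * pad > spec$window)) {
    abort("`pad` may be at most half the pooling window")
  }
  if (any(spec$window > ext + 2L * pad)) {
    abort(sprintf(
      "pooling window (%s) exceeds input spatial extent (%s)",
      paste(spec$window, collapse = "x"), paste(ext, collapse = "x")
    ))
  }
}

pool_run <- function(x, spec, pad) {
  rank <- length(dim(x))
  x5 <- as_volume(x)
  spec <- as_pool_spec(spec)
  check_pool(dim(x5), spec, pad)
  out <- cpp_pool3d_fw(as.numeric(x5), dim(x5), spec$window, spec$stride, pad)
  out$rank <- rank
  out
}

pool_shape <- function(out, v) {
  y <- array(v, dim = out$odim)
  restore_rank(y, out$rank)
}

#' Multifusion pooling
#'
#' The elementwise mean of a max-pooling and an average-pooling pass that
#' share the same window and stride:
#' `Y = (Y_max + Y_avg) / 2`. Hybridizing the two branches retains both the
#' strongest local response and the local average, which is the package's
#' downsampling operator throughout the network. Output spatial extent per
#' axis is `floor((extent + 2*pad - k) / stride) + 1`; padded cells never
#' enter a window (the average divisor counts covered cells only).
#'
#' @param x A volume (any rank accepted by [as_volume()]).
#' @param spec A [pool_spec()] (or a window vector coerced to one).
#' @param pad Nonnegative integer zero-padding per spatial axis (default 0).
#' @return The pooled volume, at the rank of the input.
#' @seealso [max_pool()], [avg_pool()]
#' @export
mf_pool <- function(x, spec, pad = 0L) {
  out <- pool_run(x, spec, pad)
  pool_shape(out, 0.5 * (out$max + out$avg))
}

#' Max pooling
#'
#' Each output cell is the maximum of its window. See [mf_pool()] for the
#' shared window/stride/padding conventions.
#'
#' @inheritParams mf_pool
#' @return The pooled volume.
#' @export
max_pool <- function(x, spec, pad = 0L) {
  out <- pool_run(x, spec, pad)
  pool_shape(out, out$max)
}

#' Average pooling
#'
#' Each output cell is the arithmetic mean of its window (divisor = number
#' of covered input cells). See [mf_pool()] for shared conventions.
#'
#' @inheritParams mf_pool
#' @return The pooled volume.
#' @export
avg_pool <- function(x, spec, pad = 0L) {
  out <- pool_run(x, spec, pad)
  pool_shape(out, out$avg)
}
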