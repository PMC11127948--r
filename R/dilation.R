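#' Dilated-convolution specification
#'
#' @param k Base kernel size: an odd positive integer.
#' @param d Dilation rate: spacing between kernel taps (1 = standard
#'   convolution).
#' @return A `dilation_spec` object.
#' @export
dilation_spec <- function(k, d = 1L) {
  k <- check_positive_int(k, "k")
  d <- check_positive_int(d, "d")
  if (length(k) != 1L || length(d) != 1L) abort("`k` and `d` must be scalars")
  if (k %% 2L == 0L) abort("base kernel size `k` must be odd")
  structure(list(k = k, d = d), class = "dilation_spec")
}

#' Effective (equivalent) kernel size of a dilated convolution
#'
#' A kernel of `k` taps spaced `d` apart spans
#' `k' = k + (k - 1) * (d - 1)` input cells, the size of the standard kernel
#' obtained by inserting `d - 1` zeros between adjacent taps. With the
#' network's defaults (`k = 3`, `d = 2`) the equivalent kernel is 5.
#'
#' @param spec A [dilation_spec()], or the base kernel size `k`.
#' @param d Dilation rate, used when `spec` is given as a bare kernel size.
#' @return The effective kernel span (integer).
#' @export
effective_kernel <- function(spec, d = 1L) {
  if (!inherits(spec, "dilation_spec")) spec <- dilation_spec(spec, d)
  as.integer(spec$k + (spec$k - 1L) * (spec$d - 1L))
}

#' Receptive field after a stack of (dilated) convolutions
#'
#' Sequentially updates a receptive field through convolution layers:
#' each layer of effective kernel `k'` grows the field by
#' `(k' - 1) * stride_product`, where `stride_product` is the product of all
#' strides applied before the stack. Starting from a single voxel
#' (`prior_rf = 1`), one dilated residual block — a `k = 3, d = 2` dilated
#' convolution followed by a standard `k = 3` convolution at unit stride —
#' reaches a receptive field of 7.
#'
#' @param prior_rf Receptive field (in input cells) entering the stack.
#' @param specs A [dilation_spec()] or a list of them, one per layer.
#' @param stride_product Cumulative stride of all preceding layers.
#' @return The receptive field after the stack (integer).
#' @export
receptive_field_after_block <- function(prior_rf, specs, stride_product = 1L) {
  prior_rf <- check_positive_int(prior_rf, "prior_rf")
  stride_product <- check_positive_int(stride_product, "stride_product")
  if (inherits(specs, "dilation_spec")) specs <- list(specs)
  rf <- prior_rf
  for (s in specs) {
    if (!inherits(s, "dilation_spec")) abort("`specs` must be dilation_spec objects")
    rf <- rf + (effective_kernel(s) - 1L) * stride_product
  }
  as.integer(rf)
}

#' Insert zeros between kernel taps
#'
#' Expands a dense kernel into the equivalent sparse standard kernel of a
#' dilated convolution: `d - 1` zeros are inserted between adjacent taps
#' along every axis. Useful for checking dilated convolutions against
#' standard ones.
#'
#' @param w A numeric vector or array (any rank) of kernel taps.
#' @param d Dilation rate.
#' @return The zero-inserted kernel; each axis of length `k` becomes
#'   `k + (k - 1) * (d - 1)`.
#' @export
dilate_kernel <- function(w, d) {
  d <- check_positive_int(d, "d")
  if (d == 1L) return(w)
  dims <- dim(w)
  if (is.null(dims)) dims <- length(w)
  newdims <- dims + (dims - 1L) * (d - 1L)
  out <- array(0, dim = newdims)
  idx <- lapply(dims, function(k) seq(1L, by = d, length.out = k))
  out[as.matrix(do.call(expand.grid, idx))] <- as.vector(w)
  if (is.null(dim(w))) dim(out) <- NULL
  out
}
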