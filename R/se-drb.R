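#' Squeeze-and-excitation specification
#'
#' @param channels Number of feature channels entering the block.
#' @param reduction Bottleneck reduction ratio `r`; must divide `channels`.
#'   The default of 16 is the standard squeeze-and-excitation choice and is
#'   configurable throughout the package.
#' @return An `se_spec` object.
#' @export
se_spec <- function(channels, reduction = 16L) {
  channels <- check_positive_int(channels, "channels")
  reduction <- check_positive_int(reduction, "reduction")
  if (channels %% reduction != 0L) {
    abort(sprintf("`reduction` (%d) must divide `channels` (%d)",
                  reduction, channels))
  }
  structure(list(channels = channels, reduction = reduction),
            class = "se_spec")
}

#' Initialize squeeze-and-excitation weights
#'
#' @param spec An [se_spec()].
#' @param seed Seed for the random initialization.
#' @return A list with the two bottleneck layers' weights
#'   (`W1`, `b1`, `W2`, `b2`).
#' @export
se_init <- function(spec, seed = 1L) {
  cr <- spec$channels %/% spec$reduction
  with_seed(seed, {
    w1 <- init_linear(spec$channels, cr)
    w2 <- init_linear(cr, spec$channels, sd = sqrt(1 / cr))
    list(W1 = w1$W, b1 = w1$b, W2 = w2$W, b2 = w2$b)
  })
}

#' Squeeze-and-excitation channel recalibration
#'
#' Per channel, a global average over the spatial axes ("squeeze") feeds a
#' two-layer bottleneck (fully connected to `channels / r`, ReLU, fully
#' connected back, sigmoid). The resulting per-channel scales in (0, 1)
#' multiply the input, letting the network re-weight channels adaptively.
#'
#' @param x A volume whose channel count equals `spec$channels`.
#' @param spec An [se_spec()].
#' @param weights Weights as produced by [se_init()].
#' @return The recalibrated volume, with the `n x channels` scale matrix
#'   attached as attribute `"scales"`.
#' @export
se_block <- function(x, spec, weights) {
  rank <- length(dim(x))
  x5 <- as_volume(x)
  if (dim(x5)[2] != spec$channels) {
    abort(sprintf("se_block expects %d channels, got %d",
                  spec$channels, dim(x5)[2]))
  }
  out <- se_fw(x5, weights)
  y <- restore_rank(out$y, rank)
  attr(y, "scales") <- out$scales
  y
}

#' Dilated residual block configuration
#'
#' The block is Conv(3, dilated) -> BN -> ReLU -> Conv(3) -> BN -> SE ->
#' residual add -> ReLU. The first convolution carries the dilation (rate 2
#' by default) with padding `d * (k - 1) / 2` so dilation changes no shapes;
#' the shortcut is the identity when input/output channels and stride agree
#' and a 1x1x1 projection convolution otherwise.
#'
#' @param in_channels,out_channels Channel counts entering/leaving the block.
#' @param stride Stride of the first convolution (2 downsamples all spatial
#'   extents by exactly half for even extents).
#' @param dilation Dilation rate of the first convolution; 1 reverts to a
#'   plain residual block (the "without dilated convolution" ablation).
#' @param use_se Keep the squeeze-and-excitation stage? `FALSE` reproduces a
#'   plain dilated residual block.
#' @param se_reduction Bottleneck ratio of the SE stage.
#' @return An `sedrb_config` object.
#' @export
sedrb_config <- function(in_channels, out_channels, stride = 1L,
                         dilation = 2L, use_se = TRUE, se_reduction = 16L) {
  cfg <- list(
    in_channels = check_positive_int(in_channels, "in_channels"),
    out_channels = check_positive_int(out_channels, "out_channels"),
    stride = check_positive_int(stride, "stride"),
    dilation = check_positive_int(dilation, "dilation"),
    use_se = isTRUE(use_se),
    se_reduction = check_positive_int(se_reduction, "se_reduction")
  )
  cfg$projection <- cfg$in_channels != cfg$out_channels || cfg$stride != 1L
  if (cfg$use_se && cfg$out_channels %% cfg$se_reduction != 0L) {
    abort("`se_reduction` must divide `out_channels`")
  }
  structure(cfg, class = "sedrb_config")
}

#' Initialize the weights of one dilated residual block
#'
#' @param config An [sedrb_config()].
#' @param seed Seed for the random initialization.
#' @return A nested weight list (`conv1`, `bn1`, `conv2`, `bn2`, optional
#'   `se` and `proj`).
#' @export
sedrb_init <- function(config, seed = 1L) {
  with_seed(seed, sedrb_init_raw(config))
}

sedrb_init_raw <- function(config) {
  wts <- list(
    conv1 = init_conv(config$out_channels, config$in_channels, c(3, 3, 3)),
    bn1 = init_bn(config$out_channels),
    conv2 = init_conv(config$out_channels, config$out_channels, c(3, 3, 3)),
    bn2 = init_bn(config$out_channels)
  )
  if (config$use_se) {
    cr <- config$out_channels %/% config$se_reduction
    w1 <- init_linear(config$out_channels, cr)
    w2 <- init_linear(cr, config$out_channels, sd = sqrt(1 / cr))
    wts$se <- list(W1 = w1$W, b1 = w1$b, W2 = w2$W, b2 = w2$b)
  }
  if (config$projection) {
    wts$proj <- init_conv(config$out_channels, config$in_channels,
                          c(1, 1, 1), bias = FALSE)
  }
  wts
}

sedrb_fw <- function(x, config, wts, training = FALSE) {
  d <- config$dilation
  c1 <- conv3d_fw(x, wts$conv1$W, wts$conv1$b, stride = config$stride,
                  pad = d, dil = d)
  b1 <- bn_fw(c1$y, wts$bn1$gamma, wts$bn1$beta, wts$bn1$rm, wts$bn1$rv,
              training)
  r1 <- relu_fw(b1$y)
  c2 <- conv3d_fw(r1$y, wts$conv2$W, wts$conv2$b, stride = 1L, pad = 1L)
  b2 <- bn_fw(c2$y, wts$bn2$gamma, wts$bn2$beta, wts$bn2$rm, wts$bn2$rv,
              training)
  branch <- b2$y
  se <- NULL
  if (config$use_se) {
    se <- se_fw(branch, wts$se)
    branch <- se$y
  }
  if (config$projection) {
    pr <- conv3d_fw(x, wts$proj$W, NULL, stride = config$stride)
    shortcut <- pr$y
  } else {
    pr <- NULL
    shortcut <- x
  }
  if (!identical(dim(branch), dim(shortcut))) {
    abort(sprintf(
      "residual add: branch is %s but shortcut is %s",
      paste(dim(branch), collapse = "x"), paste(dim(shortcut), collapse = "x")
    ))
  }
  out <- relu_fw(branch + shortcut)
  list(y = out$y,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, se = se$cache,
                    pr = pr$cache, out = out$cache, config = config),
       buffers = list(bn1 = list(rm = b1$rm, rv = b1$rv),
                      bn2 = list(rm = b2$rm, rv = b2$rv)))
}

sedrb_bw <- function(cache, wts, gy) {
  cfg <- cache$config
  g <- relu_bw(cache$out, gy)
  grads <- list()
  gbranch <- g
  gshort <- g
  if (cfg$use_se) {
    seb <- se_bw(cache$se, wts$se, gbranch)
    gbranch <- seb$gx
    grads$se <- seb[c("gW1", "gb1", "gW2", "gb2")]
    names(grads$se) <- c("W1", "b1", "W2", "b2")
  }
  b2 <- bn_bw(cache$b2, wts$bn2$gamma, gbranch)
  grads$bn2 <- list(gamma = b2$ggamma, beta = b2$gbeta)
  c2 <- conv3d_bw(cache$c2, wts$conv2$W, b2$gx)
  grads$conv2 <- list(W = c2$gW, b = c2$gb)
  gr1 <- relu_bw(cache$r1, c2$gx)
  b1 <- bn_bw(cache$b1, wts$bn1$gamma, gr1)
  grads$bn1 <- list(gamma = b1$ggamma, beta = b1$gbeta)
  c1 <- conv3d_bw(cache$c1, wts$conv1$W, b1$gx)
  grads$conv1 <- list(W = c1$gW, b = c1$gb)
  if (cfg$projection) {
    pr <- conv3d_bw(cache$pr, wts$proj$W, gshort)
    grads$proj <- list(W = pr$gW)
    gx <- c1$gx + pr$gx
  } else {
    gx <- c1$gx + gshort
  }
  list(gx = gx, grads = grads)
}

#' Apply one squeeze-and-excitation dilated residual block
#'
#' Functional forward pass of a single block (evaluation mode: batch
#' normalization uses the running statistics stored in `weights`). See
#' [sedrb_config()] for the stage order.
#'
#' @param x A volume with `config$in_channels` channels.
#' @param config An [sedrb_config()].
#' @param weights Weights as produced by [sedrb_init()].
#' @return The block output volume.
#' @export
se_drb <- function(x, config, weights) {
  rank <- length(dim(x))
  x5 <- as_volume(x)
  if (dim(x5)[2] != config$in_channels) {
    abort(sprintf("se_drb expects %d input channels, got %d",
                  config$in_channels, dim(x5)[2]))
  }
  restore_rank(sedrb_fw(x5, config, weights)$y, rank)
}
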