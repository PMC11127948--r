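# Differentiable primitives: each *_fw returns list(y, cache) and the
# matching *_bw maps the upstream gradient back to inputs and parameters.
# Volumes are (n, c, d, h, w) arrays; convolution and pooling run in
# compiled direct kernels (no im2col intermediates).

conv3d_fw <- function(x, W, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xd <- dim(x)
  kd <- dim(W)
  if (xd[2] != kd[2]) {
    abort(sprintf("conv expects %d input channels, got %d", kd[2], xd[2]))
  }
  out <- cpp_conv3d_fw(x, xd, W, kd, b, stride, pad, dil)
  y <- out$y
  dim(y) <- out$odim
  list(y = y, cache = list(x = x, xd = xd, stride = stride, pad = pad,
                           dil = dil, has_bias = !is.null(b)))
}

conv3d_bw <- function(cache, W, gy, need_gx = TRUE) {
  xd <- cache$xd
  kd <- dim(W)
  od <- dim(gy)
  gW <- array(cpp_conv3d_gw(cache$x, xd, gy, kd, cache$stride, cache$pad,
                            cache$dil), dim = kd)
  gb <- NULL
  if (cache$has_bias) {
    # per-output-channel sum; channel is the second-fastest axis
    gb <- colSums(matrix(rowSums(matrix(gy, nrow = od[1] * od[2])),
                         nrow = od[1]))
  }
  gx <- NULL
  if (need_gx) {
    gx <- array(cpp_conv3d_gx(gy, xd, W, kd, cache$stride, cache$pad,
                              cache$dil), dim = xd)
  }
  list(gx = gx, gW = gW, gb = gb)
}

# Channel-wise batch normalization over (n, d, h, w). Uses biased batch
# variance; running statistics follow the usual exponential moving average.
# Channel is the second-fastest axis, so per-channel quantities broadcast
# as rep(rep(q, each = n), times = spatial) without transposing the volume.
bn_expand <- function(q, xd) {
  rep(rep(q, each = xd[1]), times = prod(xd[3:5]))
}

# per-channel mean of an (n, c, d, h, w) array without materializing aperm
bn_channel_mean <- function(x, xd) {
  colMeans(matrix(rowSums(matrix(x, nrow = xd[1] * xd[2])), nrow = xd[1])) /
    prod(xd[3:5])
}

bn_fw <- function(x, gamma, beta, rm, rv, training = FALSE,
                  momentum = 0.1, eps = 1e-5) {
  xd <- dim(x)
  if (training) {
    mu <- bn_channel_mean(x, xd)
    v <- bn_channel_mean(x * x, xd) - mu^2
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm
    v <- rv
  }
  sdv <- sqrt(v + eps)
  xhat <- (x - bn_expand(mu, xd)) / bn_expand(sdv, xd)
  y <- xhat * bn_expand(gamma, xd) + bn_expand(beta, xd)
  list(y = y,
       cache = list(xhat = xhat, sdv = sdv, xd = xd, training = training),
       rm = rm, rv = rv)
}

bn_bw <- function(cache, gamma, gy) {
  xd <- cache$xd
  M <- xd[1] * prod(xd[3:5]) # cells per channel
  ggamma <- bn_channel_mean(gy * cache$xhat, xd) * M
  gbeta <- bn_channel_mean(gy, xd) * M
  gxhat <- gy * bn_expand(gamma, xd)
  if (cache$training) {
    gx <- (gxhat - bn_expand(gbeta * gamma / M, xd) -
             cache$xhat * bn_expand(ggamma * gamma / M, xd)) /
      bn_expand(cache$sdv, xd)
  } else {
    gx <- gxhat / bn_expand(cache$sdv, xd)
  }
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bw <- function(cache, gy) gy * cache

elu_fw <- function(x, alpha = 1) {
  y <- ifelse(x > 0, x, alpha * (exp(pmin(x, 0)) - 1))
  dim(y) <- dim(x)
  list(y = y, cache = list(x = x, y = y, alpha = alpha))
}
elu_bw <- function(cache, gy) {
  gy * ifelse(cache$x > 0, 1, cache$y + cache$alpha)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

linear_fw <- function(x, W, b) {
  list(y = sweep(x %*% W, 2, b, "+"), cache = x)
}
linear_bw <- function(cache, W, gy) {
  list(gx = tcrossprod(gy, W), gW = crossprod(cache, gy), gb = colSums(gy))
}

# Hybrid pooling as a trainable layer. variant "mf" is the mean of the max
# and average branches; "max" keeps only the max branch (ablation).
pool_layer_fw <- function(x, window, stride, pad, variant = "mf") {
  xd <- dim(x)
  out <- cpp_pool3d_fw(x, xd, window, stride, pad)
  y <- if (variant == "mf") 0.5 * (out$max + out$avg) else out$max
  list(y = array(y, dim = out$odim),
       cache = list(argmax = out$argmax, xd = xd, window = window,
                    stride = stride, pad = pad, variant = variant))
}

pool_layer_bw <- function(cache, gy) {
  xlen <- prod(cache$xd)
  g <- as.numeric(gy)
  if (cache$variant == "mf") {
    gx <- cpp_pool3d_bw_max(cache$argmax, 0.5 * g, xlen) +
      cpp_pool3d_bw_avg(0.5 * g, cache$xd, cache$window, cache$stride,
                        cache$pad)
  } else {
    gx <- cpp_pool3d_bw_max(cache$argmax, g, xlen)
  }
  array(gx, dim = cache$xd)
}

# Global hybrid pooling: per (n, c), the mean of the global max and global
# average over all spatial positions; yields an n x c feature matrix of
# fixed length for any input size.
gpool_fw <- function(x, variant = "mf") {
  xd <- dim(x)
  S <- prod(xd[3:5])
  xm <- matrix(x, nrow = xd[1] * xd[2])
  amax <- max.col(xm, ties.method = "first")
  gmax <- xm[cbind(seq_len(nrow(xm)), amax)]
  v <- if (variant == "mf") 0.5 * (gmax + rowMeans(xm)) else gmax
  list(y = matrix(v, nrow = xd[1]),
       cache = list(xd = xd, S = S, amax = amax, variant = variant))
}

gpool_bw <- function(cache, gy) {
  xd <- cache$xd
  S <- cache$S
  g <- as.numeric(gy) # length n*c, same (n, c) order as the pooled matrix
  gxm <- matrix(0, nrow = xd[1] * xd[2], ncol = S)
  if (cache$variant == "mf") {
    gxm[] <- 0.5 * g / S
    gxm[cbind(seq_along(g), cache$amax)] <-
      gxm[cbind(seq_along(g), cache$amax)] + 0.5 * g
  } else {
    gxm[cbind(seq_along(g), cache$amax)] <- g
  }
  array(gxm, dim = xd)
}

# Squeeze-and-excitation: global-average squeeze, bottleneck excitation
# (FC -> ReLU -> FC -> sigmoid), then per-channel rescaling of the input.
se_fw <- function(x, wts) {
  xd <- dim(x)
  S <- prod(xd[3:5])
  xm <- matrix(x, nrow = xd[1] * xd[2])
  z <- matrix(rowMeans(xm), nrow = xd[1]) # n x c squeeze
  a1 <- sweep(z %*% wts$W1, 2, wts$b1, "+")
  r1 <- pmax(a1, 0)
  a2 <- sweep(r1 %*% wts$W2, 2, wts$b2, "+")
  s <- sigmoid(a2) # n x c channel scales in (0, 1)
  y <- x * rep(as.numeric(s), times = S)
  list(y = y, scales = s,
       cache = list(x = x, z = z, a1 = a1, r1 = r1, s = s, S = S, xd = xd))
}

se_bw <- function(cache, wts, gy) {
  S <- cache$S
  svec <- rep(as.numeric(cache$s), times = S)
  gs <- matrix(rowSums(matrix(gy * cache$x, nrow = prod(cache$xd[1:2]))),
               nrow = cache$xd[1])
  gx <- gy * svec
  ga2 <- gs * cache$s * (1 - cache$s)
  gW2 <- crossprod(cache$r1, ga2)
  gb2 <- colSums(ga2)
  gr1 <- ga2 %*% t(wts$W2)
  ga1 <- gr1 * (cache$a1 > 0)
  gW1 <- crossprod(cache$z, ga1)
  gb1 <- colSums(ga1)
  gz <- ga1 %*% t(wts$W1)
  gx <- gx + rep(as.numeric(gz), times = S) / S
  dim(gx) <- cache$xd
  list(gx = gx, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

# Parameter initializers (He-style for conv/linear going into ReLU).
init_conv <- function(cout, cin, k, bias = TRUE) {
  fan_in <- cin * prod(k)
  W <- array(rnorm(cout * cin * prod(k), sd = sqrt(2 / fan_in)),
             dim = c(cout, cin, k))
  out <- list(W = W)
  if (bias) out$b <- rep(0, cout)
  out
}

init_linear <- function(nin, nout, sd = sqrt(2 / max(nin, 1))) {
  list(W = matrix(rnorm(nin * nout, sd = sd), nrow = nin), b = rep(0, nout))
}

init_bn <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C), rm = rep(0, C), rv = rep(1, C))
}
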