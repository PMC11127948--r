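# Brute-force reference implementations, written as plain loops so they are
# independent of the package's vectorized/compiled code paths.

# Sliding-window pooling by exhaustive window enumeration.
pool_oracle <- function(x, window, stride, pad = 0L,
                        type = c("max", "avg", "mf")) {
  type <- match.arg(type)
  d <- dim(x)
  stopifnot(length(d) == 5L)
  oext <- (d[3:5] + 2L * pad - window) %/% stride + 1L
  y <- array(NA_real_, dim = c(d[1], d[2], oext))
  for (n in seq_len(d[1])) for (c in seq_len(d[2])) {
    for (od in seq_len(oext[1])) for (oh in seq_len(oext[2])) {
      for (ow in seq_len(oext[3])) {
        vals <- c()
        for (a in seq_len(window[1])) for (b in seq_len(window[2])) {
          for (g in seq_len(window[3])) {
            di <- (od - 1L) * stride - pad + a
            hi <- (oh - 1L) * stride - pad + b
            wi <- (ow - 1L) * stride - pad + g
            if (di >= 1 && di <= d[3] && hi >= 1 && hi <= d[4] &&
                wi >= 1 && wi <= d[5]) {
              vals <- c(vals, x[n, c, di, hi, wi])
            }
          }
        }
        y[n, c, od, oh, ow] <- switch(type,
          max = max(vals),
          avg = mean(vals),
          mf = (max(vals) + mean(vals)) / 2
        )
      }
    }
  }
  y
}

# Direct convolution by explicit loops over output cells and kernel taps.
conv_oracle <- function(x, W, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xd <- dim(x)
  kd <- dim(W)
  span <- (kd[3:5] - 1L) * dil + 1L
  oext <- (xd[3:5] + 2L * pad - span) %/% stride + 1L
  y <- array(0, dim = c(xd[1], kd[1], oext))
  for (n in seq_len(xd[1])) for (co in seq_len(kd[1])) {
    for (od in seq_len(oext[1])) for (oh in seq_len(oext[2])) {
      for (ow in seq_len(oext[3])) {
        acc <- if (is.null(b)) 0 else b[co]
        for (ci in seq_len(kd[2])) {
          for (a in seq_len(kd[3])) for (bb in seq_len(kd[4])) {
            for (g in seq_len(kd[5])) {
              di <- (od - 1L) * stride - pad + (a - 1L) * dil + 1L
              hi <- (oh - 1L) * stride - pad + (bb - 1L) * dil + 1L
              wi <- (ow - 1L) * stride - pad + (g - 1L) * dil + 1L
              if (di >= 1 && di <= xd[3] && hi >= 1 && hi <= xd[4] &&
                  wi >= 1 && wi <= xd[5]) {
                acc <- acc + x[n, ci, di, hi, wi] * W[co, ci, a, bb, g]
              }
            }
          }
        }
        y[n, co, od, oh, ow] <- acc
      }
    }
  }
  y
}

# Squeeze-and-excitation by explicit loops: GAP -> FC -> ReLU -> FC ->
# sigmoid -> channel-wise scaling.
se_oracle <- function(x, wts) {
  xd <- dim(x)
  y <- array(NA_real_, dim = xd)
  for (n in seq_len(xd[1])) {
    z <- vapply(seq_len(xd[2]), function(c) mean(x[n, c, , , ]), numeric(1))
    a1 <- as.numeric(z %*% wts$W1) + wts$b1
    r1 <- pmax(a1, 0)
    a2 <- as.numeric(r1 %*% wts$W2) + wts$b2
    s <- 1 / (1 + exp(-a2))
    for (c in seq_len(xd[2])) y[n, c, , , ] <- x[n, c, , , ] * s[c]
  }
  y
}

rand_volume <- function(n = 1L, c = 1L, ext = c(4L, 4L, 4L)) {
  array(rnorm(n * c * prod(ext)), dim = c(n, c, ext))
}

# A 4x4 spatial map with values 1..16 laid out row-major, as a 5-axis
# volume (depth extent 1).
map_1to16 <- function() {
  x <- array(0, dim = c(1, 1, 1, 4, 4))
  for (h in 1:4) for (w in 1:4) x[1, 1, 1, h, w] <- (h - 1) * 4 + w
  x
}

# Central finite differences of a scalar function at x.
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Small configs used across tests: a slim architecture that keeps forward
# and backward passes fast while exercising every stage.
slim_config <- function(task = "score_regression", ...) {
  model_config(task = task, stage_widths = c(4L, 8L, 8L, 8L),
               blocks_per_stage = c(1L, 1L, 1L, 1L), se_reduction = 4L,
               fusion_dim = 8L, ...)
}
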