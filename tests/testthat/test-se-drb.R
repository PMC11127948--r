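test_that("zero pre-sigmoid excitation halves the input (sigmoid(0) = 0.5)", {
  sp <- se_spec(4L, 2L)
  wts <- list(W1 = matrix(0, 4, 2), b1 = rep(0, 2),
              W2 = matrix(0, 2, 4), b2 = rep(0, 4))
  x <- rand_volume(2, 4, c(3, 3, 3))
  y <- se_block(x, sp, wts)
  expect_equal(as.numeric(y), as.numeric(0.5 * x))
})

test_that("the squeeze vector equals per-channel constants for constant channels", {
  x <- array(0, dim = c(1, 3, 2, 2, 2))
  for (c in 1:3) x[1, c, , , ] <- c * 1.5
  out <- mfsedrn:::se_fw(x, se_init(se_spec(3L, 1L), seed = 2))
  expect_equal(as.numeric(out$cache$z), c(1.5, 3.0, 4.5))
})

test_that("se_block matches the loop-based oracle on random inputs and weights", {
  set.seed(55)
  for (i in 1:20) {
    C <- sample(c(2L, 4L, 6L), 1)
    r <- if (C %% 2L == 0L) 2L else 1L
    x <- rand_volume(sample(1:3, 1), C, sample(2:4, 3, replace = TRUE))
    sp <- se_spec(C, r)
    wts <- se_init(sp, seed = i)
    expect_equal(as.numeric(se_block(x, sp, wts)),
                 as.numeric(se_oracle(x, wts)), tolerance = 1e-12)
  }
})

test_that("excitation scales lie in (0,1), so output norm never exceeds input norm per channel", {
  set.seed(66)
  x <- rand_volume(2, 4, c(3, 3, 3))
  sp <- se_spec(4L, 2L)
  wts <- se_init(sp, seed = 9)
  y <- se_block(x, sp, wts)
  sc <- attr(y, "scales")
  expect_true(all(sc > 0 & sc < 1))
  for (n in 1:2) for (c in 1:4) {
    expect_lte(sum(y[n, c, , , ]^2), sum(x[n, c, , , ]^2))
  }
})

test_that("se_block is positively homogeneous only with frozen excitation", {
  set.seed(3)
  x <- rand_volume(1, 4, c(3, 3, 3))
  sp <- se_spec(4L, 2L)
  wts <- se_init(sp, seed = 4)
  y1 <- se_block(x, sp, wts)
  y2 <- se_block(2 * x, sp, wts)
  # adaptive excitation: doubling the input does not double the output
  expect_gt(max(abs(as.numeric(y2) - 2 * as.numeric(y1))), 1e-8)
  # frozen scales: rescaling is exactly linear
  frozen <- attr(y1, "scales")
  manual <- (2 * x) * rep(as.numeric(frozen), times = prod(dim(x)[3:5]))
  expect_equal(as.numeric(manual), 2 * as.numeric(y1))
})

test_that("se_block rejects mismatched channel counts", {
  x <- rand_volume(1, 3, c(2, 2, 2))
  expect_error(se_block(x, se_spec(4L, 2L), se_init(se_spec(4L, 2L))),
               "channels")
  expect_error(se_spec(6L, 4L), "divide")
})

test_that("a zeroed residual branch reduces the block to ReLU of the shortcut", {
  cfg <- sedrb_config(3L, 3L, stride = 1L, dilation = 2L, use_se = TRUE,
                      se_reduction = 3L)
  wts <- sedrb_init(cfg, seed = 1)
  # zero conv2 => branch is BN(0) + SE; with zero bn2 gamma/beta the branch
  # contributes nothing, leaving ReLU(identity shortcut)
  wts$conv2$W[] <- 0
  wts$conv2$b[] <- 0
  wts$bn2$gamma[] <- 0
  wts$bn2$beta[] <- 0
  x <- rand_volume(2, 3, c(4, 4, 4))
  y <- se_drb(x, cfg, wts)
  expect_equal(as.numeric(y), as.numeric(pmax(x, 0)), tolerance = 1e-12)
})

test_that("with all-zero weights and unit BN the block is a residual passthrough", {
  cfg <- sedrb_config(2L, 2L, use_se = TRUE, se_reduction = 2L)
  wts <- sedrb_init(cfg, seed = 1)
  for (p in c("conv1", "conv2")) {
    wts[[p]]$W[] <- 0
    wts[[p]]$b[] <- 0
  }
  for (p in c("W1", "b1", "W2", "b2")) wts$se[[p]][] <- 0
  wts$bn1$beta[] <- 0
  wts$bn2$beta[] <- 0
  x <- rand_volume(1, 2, c(4, 4, 4))
  y <- se_drb(x, cfg, wts)
  expect_equal(as.numeric(y), as.numeric(pmax(x, 0)), tolerance = 1e-6)
})

test_that("stride-2 blocks halve every spatial extent", {
  cfg <- sedrb_config(2L, 4L, stride = 2L, se_reduction = 2L)
  wts <- sedrb_init(cfg, seed = 2)
  x <- rand_volume(1, 2, c(8, 6, 4))
  expect_equal(dim(se_drb(x, cfg, wts)), c(1, 4, 4, 3, 2))
})

test_that("disabling SE equals forcing the excitation scales to one", {
  set.seed(21)
  x <- rand_volume(2, 4, c(4, 4, 4))
  cfg_se <- sedrb_config(4L, 4L, use_se = TRUE, se_reduction = 2L)
  wts <- sedrb_init(cfg_se, seed = 5)
  # saturate the excitation at 1 via a huge positive bias
  wts_sat <- wts
  wts_sat$se$b2[] <- 1e4
  cfg_no <- sedrb_config(4L, 4L, use_se = FALSE)
  wts_no <- wts[c("conv1", "bn1", "conv2", "bn2")]
  expect_equal(as.numeric(se_drb(x, cfg_se, wts_sat)),
               as.numeric(se_drb(x, cfg_no, wts_no)), tolerance = 1e-9)
})

test_that("dilated and plain first convolutions differ unless the input makes them agree", {
  cfg_d <- sedrb_config(2L, 2L, dilation = 2L, use_se = FALSE)
  cfg_p <- sedrb_config(2L, 2L, dilation = 1L, use_se = FALSE)
  wts <- sedrb_init(cfg_d, seed = 7)
  x <- rand_volume(1, 2, c(6, 6, 6))
  expect_gt(max(abs(se_drb(x, cfg_d, wts) - se_drb(x, cfg_p, wts))), 1e-8)
  # constant input: dilation cannot matter in the interior, but padding
  # differs at the boundary, so restrict to the center cell
  xc <- array(1, dim = c(1, 2, 9, 9, 9))
  yd <- se_drb(xc, cfg_d, wts)
  yp <- se_drb(xc, cfg_p, wts)
  expect_equal(yd[1, , 5, 5, 5], yp[1, , 5, 5, 5], tolerance = 1e-9)
})

test_that("shape mismatches raise errors naming the offending stage", {
  cfg <- sedrb_config(3L, 3L, se_reduction = 3L)
  wts <- sedrb_init(cfg, seed = 1)
  expect_error(se_drb(rand_volume(1, 2, c(4, 4, 4)), cfg, wts),
               "input channels")
})
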