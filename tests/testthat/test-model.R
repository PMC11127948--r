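test_that("the default architecture censuses to 36 layers", {
  cen <- layer_census(model_config())
  expect_identical(cen$total, 36L)
  expect_identical(cen$conv_in_blocks, 32L)
  expect_identical(cen$se_drb, 16L)
  expect_identical(cen$mf_pool, 2L)
  expect_identical(cen$stem_conv, 1L)
  expect_identical(cen$fusion, 1L)
})

test_that("census counts follow the block plan and its invariants", {
  cen <- layer_census(model_config(blocks_per_stage = c(1L, 0L, 0L, 0L)))
  expect_identical(cen$conv_in_blocks, 2L)
  expect_identical(cen$se_drb, 1L)
  set.seed(10)
  for (i in 1:50) {
    bp <- sample(0:5, 4, replace = TRUE)
    if (sum(bp) == 0) bp[1] <- 1L
    cen <- layer_census(model_config(blocks_per_stage = as.integer(bp)))
    expect_identical(cen$conv_in_blocks, 2L * cen$se_drb)
    expect_identical(cen$total, cen$conv_in_blocks + cen$stem_conv +
                       cen$mf_pool + cen$fusion)
  }
})

test_that("ablation flags reshape the census as designed", {
  base <- model_config()
  cen_nose <- layer_census(ablation_variant(base, "Without SE"))
  expect_identical(cen_nose$aux$se_stages, 0L)
  expect_identical(cen_nose$conv_in_blocks, 32L) # conv counts unchanged
  cen_nomf <- layer_census(ablation_variant(base, "Without MF-pool"))
  expect_identical(cen_nomf$mf_pool, 0L)
  expect_identical(cen_nomf$aux$max_pool_only, 2L)
  cen_nofu <- layer_census(ablation_variant(base, "Without multi-feature fusion"))
  expect_identical(cen_nofu$fusion, 0L)
  # the five ablations plus the full model give distinct signatures
  sigs <- vapply(ablation_groups(), function(g) {
    cfg <- ablation_variant(base, g)
    paste(cfg$no_dc, cfg$no_se, cfg$no_mf_pool, cfg$no_fusion)
  }, character(1))
  expect_identical(length(unique(sigs)), 6L)
  expect_error(ablation_variant(base, "Without everything"), "unknown")
})

test_that("the dilation ablation reverts the blocks' first convolution to k' = 3", {
  cfg <- ablation_variant(slim_config(), "Without DC")
  m <- build_model(cfg, seed = 1)
  blk <- m$nodes[[which(vapply(m$nodes, `[[`, "", "type") == "sedrb")[1]]]
  expect_identical(effective_kernel(3L, blk$config$dilation), 3L)
  m_full <- build_model(slim_config(), seed = 1)
  blk_full <- m_full$nodes[[which(vapply(m_full$nodes, `[[`, "", "type") == "sedrb")[1]]]
  expect_identical(effective_kernel(3L, blk_full$config$dilation), 5L)
})

test_that("forward pass returns finite outputs of the right shape for both tasks", {
  set.seed(2)
  x <- array(rnorm(2 * 16^3), c(2, 1, 16, 16, 16))
  tab <- matrix(rnorm(2 * 8), 2)
  m_reg <- build_model(slim_config("score_regression"), seed = 1)
  out <- predict(m_reg, x, tab)
  expect_length(out, 2)
  expect_true(all(is.finite(out)))
  m_cls <- build_model(slim_config("conversion_classification"), seed = 1)
  logits <- predict(m_cls, x, tab, type = "logits")
  expect_equal(dim(logits), c(2L, 2L))
  probs <- predict(m_cls, x, tab)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("forward pass is deterministic given fixed weights and input", {
  set.seed(3)
  x <- array(rnorm(16^3), c(1, 1, 16, 16, 16))
  tab <- matrix(rnorm(8), 1)
  m <- build_model(slim_config(), seed = 7)
  expect_identical(predict(m, x, tab), predict(m, x, tab))
  m2 <- build_model(slim_config(), seed = 7)
  expect_identical(predict(m, x, tab), predict(m2, x, tab))
})

test_that("every ablation variant builds and runs forward on the same input shapes", {
  set.seed(4)
  x <- array(rnorm(16^3), c(1, 1, 16, 16, 16))
  tab <- matrix(rnorm(8), 1)
  for (g in ablation_groups()) {
    cfg <- ablation_variant(slim_config(), g)
    m <- build_model(cfg, seed = 1)
    tb <- if (cfg$no_fusion) NULL else tab
    expect_true(all(is.finite(predict(m, x, tb))), info = g)
  }
})

test_that("the full model has strictly more parameters than no-SE and no-fusion variants", {
  full <- n_params(build_model(slim_config(), seed = 1))
  no_se <- n_params(build_model(ablation_variant(slim_config(), "Without SE"),
                                seed = 1))
  no_fu <- n_params(build_model(
    ablation_variant(slim_config(), "Without multi-feature fusion"), seed = 1))
  expect_gt(full, no_se)
  expect_gt(full, no_fu)
})

test_that("removing hybrid pooling changes nothing when max and average branches coincide", {
  # a constant feature map downstream of the stem makes max = avg in every
  # pooling window, so the mf and max-only pools agree exactly
  x <- array(1, dim = c(1, 2, 6, 6, 6))
  y_mf <- mfsedrn:::pool_layer_fw(x, c(3L, 3L, 3L), 2L, 1L, "mf")$y
  y_mx <- mfsedrn:::pool_layer_fw(x, c(3L, 3L, 3L), 2L, 1L, "max")$y
  expect_equal(y_mf, y_mx)
  g_mf <- mfsedrn:::gpool_fw(x, "mf")$y
  g_mx <- mfsedrn:::gpool_fw(x, "max")$y
  expect_equal(g_mf, g_mx)
})

test_that("fusion concatenates image and tabular features through FC + ELU", {
  img <- matrix(rnorm(6), 2)
  tab <- matrix(rnorm(8), 2)
  W <- diag(1, 7, 7)
  wts <- list(W = W[, 1:7], b = rep(0, 7))
  f <- fuse_features(img, tab, wts)
  expect_equal(ncol(f), 7) # fused width
  # identity weights expose the concatenation: ELU of the raw inputs
  z <- cbind(img, tab)[, 1:7]
  expect_equal(f, ifelse(z > 0, z, exp(pmin(z, 0)) - 1), tolerance = 1e-12)
  # ELU closed-form values
  e <- mfsedrn:::elu_fw(c(-1, 0, 1))$y
  expect_equal(e, c(exp(-1) - 1, 0, 1))
  expect_error(fuse_features(img, tab[1, , drop = FALSE], wts), "differ")
})

test_that("dropping the tabular branch leaves image coordinates of the head input unchanged", {
  set.seed(9)
  img <- matrix(rnorm(8), 2)
  tab <- matrix(0, 2, 3)
  W_full <- matrix(rnorm(7 * 5), 7, 5)
  b <- rnorm(5)
  W_img <- W_full[1:4, ]
  f_full <- fuse_features(img, tab, list(W = W_full, b = b))
  f_img <- fuse_features(img, NULL, list(W = W_img, b = b), no_fusion = TRUE)
  # zero tabular input contributes nothing, so both paths agree
  expect_equal(f_full, f_img, tolerance = 1e-12)
})

test_that("configs survive a YAML round trip and checkpoints restore predictions", {
  cfg <- slim_config("conversion_classification", no_se = TRUE)
  path <- tempfile(fileext = ".yaml")
  write_model_config(cfg, path)
  cfg2 <- read_model_config(path)
  expect_equal(unclass(cfg), unclass(cfg2)[names(unclass(cfg))])
  m <- build_model(cfg, seed = 3)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  x <- array(rnorm(16^3), c(1, 1, 16, 16, 16))
  tab <- matrix(rnorm(8), 1)
  expect_identical(predict(m, x, tab), predict(m2, x, tab))
})

test_that("census exports as JSON with the headline counts", {
  js <- jsonlite::fromJSON(census_json(model_config()))
  expect_equal(js$total, 36)
  expect_equal(js$conv_in_blocks, 32)
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(stage_widths = c(64L, 128L, 256L)), "length 4")
  expect_error(model_config(stage_widths = c(60L, 128L, 256L, 512L)),
               "se_reduction")
  expect_error(build_model(list()), "model_config")
})
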