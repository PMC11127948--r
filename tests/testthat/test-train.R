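# Fast training-engine checks on deliberately tiny models and volumes.

tiny_cfg <- function(task = "score_regression") {
  model_config(task = task, stage_widths = c(2L, 4L, 4L, 4L),
               blocks_per_stage = c(1L, 1L, 0L, 1L), se_reduction = 2L,
               fusion_dim = 4L, tabular_dim = 3L)
}

tiny_data <- function(n = 4L, seed = 1L, task = "score_regression") {
  set.seed(seed)
  list(
    x = array(rnorm(n * 8^3), c(n, 1, 8, 8, 8)),
    tab = matrix(rnorm(n * 3), n),
    y = if (task == "score_regression") rnorm(n) else rep_len(0:1, n)
  )
}

test_that("folds partition the ids, are seed-stable and differ across repeats", {
  ids <- sprintf("S%02d", 1:10)
  f <- make_folds(ids, folds = 5L, seed = 3L)
  expect_identical(nrow(f), 5L)
  expect_true(all(vapply(f$val, length, 0L) == 2L))
  expect_setequal(unlist(f$val), ids)
  expect_identical(length(unique(unlist(f$val))), 10L)
  for (r in seq_len(5)) {
    expect_identical(sort(c(f$train[[r]], f$val[[r]])), sort(ids))
    expect_length(intersect(f$train[[r]], f$val[[r]]), 0L)
  }
  expect_identical(make_folds(ids, folds = 5L, seed = 3L), f)
  f2 <- make_folds(ids, folds = 5L, repeats = 2L, seed = 3L)
  expect_false(identical(sort(f2$val[[1]]), sort(f2$val[[6]])) &&
                 identical(sort(f2$val[[2]]), sort(f2$val[[7]])) &&
                 identical(sort(f2$val[[3]]), sort(f2$val[[8]])))
  expect_error(make_folds(ids[1:3], folds = 5L), "at least")
})

test_that("stratified folds allocate positives proportionally (exact for 25% of 20)", {
  ids <- sprintf("S%02d", 1:20)
  labels <- rep(c(1, 0, 0, 0), 5)
  f <- make_folds(ids, labels = labels, folds = 5L, seed = 7L)
  for (r in seq_len(5)) {
    pos <- sum(labels[match(f$val[[r]], ids)] == 1)
    expect_identical(pos, 1L)
  }
})

test_that("backpropagated gradients match finite differences across all layer types", {
  cfg <- tiny_cfg("conversion_classification")
  m <- build_model(cfg, seed = 5)
  dd <- tiny_data(2L, seed = 11, task = "conversion_classification")
  lossfn <- function(model) {
    fwd <- mfsedrn:::model_forward(model, dd$x, dd$tab, training = TRUE)
    mfsedrn:::loss_grad(fwd$out, dd$y, "cross_entropy")$loss
  }
  fwd <- mfsedrn:::model_forward(m, dd$x, dd$tab, training = TRUE)
  lg <- mfsedrn:::loss_grad(fwd$out, dd$y, "cross_entropy")
  gr <- mfsedrn:::model_backward(m, fwd, lg$grad)
  set.seed(2)
  for (nm in names(m$params)) {
    idx <- sample(seq_along(m$params[[nm]]), min(2L, length(m$params[[nm]])))
    for (i in idx) {
      eps <- 1e-5
      m2 <- m
      m2$params[[nm]][i] <- m$params[[nm]][i] + eps
      lp <- lossfn(m2)
      m2$params[[nm]][i] <- m$params[[nm]][i] - eps
      lm_ <- lossfn(m2)
      num <- (lp - lm_) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("a zero learning rate leaves all weights unchanged", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 2)
  dd <- tiny_data(4L)
  tc <- train_config("score_regression", epochs = 3L, batch_size = 2L,
                     lr = 0, seed = 1L)
  fit <- train(m, dd, tc)
  expect_identical(fit$model$params, m$params)
})

test_that("a slim model memorizes a single repeated training sample", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 3)
  set.seed(4)
  x1 <- array(rnorm(8^3), c(1, 1, 8, 8, 8))
  dd <- list(x = x1[rep(1, 4), , , , , drop = FALSE],
             tab = matrix(rnorm(3), 4, 3, byrow = TRUE), y = rep(0.7, 4))
  tc <- train_config("score_regression", epochs = 200L, batch_size = 4L,
                     lr = 1e-2, l1_coeff = 0, l2_coeff = 0, seed = 1L)
  fit <- train(m, dd, tc)
  pred <- predict(fit$model, dd$x, dd$tab)
  expect_lt(mean((pred - 0.7)^2), 1e-3)
})

test_that("strong L1 regularization on zero-signal data drives weights toward zero", {
  dd <- tiny_data(6L, seed = 9)
  dd$y <- rep(0, 6) # no signal
  run_l1 <- function(l1) {
    m <- build_model(tiny_cfg(), seed = 8)
    tc <- train_config("score_regression", epochs = 20L, batch_size = 3L,
                       lr = 1e-3, l1_coeff = l1, l2_coeff = 0, seed = 5L)
    fit <- train(m, dd, tc)
    w <- unlist(fit$model$params[grepl("\\.W$", names(fit$model$params))])
    mean(abs(w) < 1e-4)
  }
  expect_gt(run_l1(5e-2), run_l1(0))
})

test_that("training histories are reproducible under a fixed seed", {
  dd <- tiny_data(4L, seed = 6)
  tc <- train_config("score_regression", epochs = 4L, batch_size = 2L,
                     lr = 1e-3, seed = 11L)
  f1 <- train(build_model(tiny_cfg(), seed = 1), dd, tc)
  f2 <- train(build_model(tiny_cfg(), seed = 1), dd, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("a non-finite loss aborts with the epoch and batch named", {
  m <- build_model(tiny_cfg(), seed = 1)
  dd <- tiny_data(2L)
  dd$y <- c(Inf, 1)
  tc <- train_config("score_regression", epochs = 1L, batch_size = 2L,
                     seed = 1L)
  expect_error(train(m, dd, tc), "epoch 1, batch 1")
})

test_that("an injected perfect-oracle predictor yields zero error through the harness", {
  ch <- generate_cohort(cohort_params(n = c(NC = 10L, MCI = 20L, AD = 10L),
                                      seed = 31L))
  oracle <- function(train_df, val_df) as.numeric(val_df$.target)
  run <- run_experiment(ch, "score_regression", "M06", score = "MMSE",
                        train_cfg = train_config("score_regression",
                                                 folds = 4L),
                        predictor = oracle, seed = 2L)
  expect_equal(run$pooled$rmse, 0)
  expect_equal(run$pooled$mae, 0)
  cls_oracle <- function(train_df, val_df) {
    as.numeric(val_df$.target == "pMCI")
  }
  ch2 <- generate_cohort(cohort_params(n = c(NC = 0L, MCI = 60L, AD = 0L),
                                       seed = 32L))
  run2 <- run_experiment(ch2, "conversion_classification", "M36",
                         train_cfg = train_config("conversion_classification",
                                                  folds = 4L),
                         predictor = cls_oracle, seed = 2L)
  expect_equal(run2$pooled$acc, 1)
  expect_equal(run2$pooled$auc, 1)
})

test_that("subjects lacking the horizon target are excluded and folds hash identically across reruns", {
  ch <- generate_cohort(cohort_params(n = c(NC = 10L, MCI = 30L, AD = 10L),
                                      seed = 33L))
  oracle <- function(train_df, val_df) as.numeric(val_df$.target)
  r1 <- run_experiment(ch, "score_regression", "M36", score = "ADAS11",
                       train_cfg = train_config("score_regression", folds = 3L),
                       predictor = oracle, seed = 9L)
  expect_identical(r1$n, sum(!is.na(ch$adas11_m36)))
  r2 <- run_experiment(ch, "score_regression", "M36", score = "ADAS11",
                       train_cfg = train_config("score_regression", folds = 3L),
                       predictor = oracle, seed = 9L)
  expect_identical(r1$split_hash, r2$split_hash)
  expect_error(run_experiment(ch, "score_regression", "M36", score = "MMSE",
                              horizon = "M48"), "not valid")
})

test_that("run directories capture configs, splits, metrics and predictions", {
  ch <- generate_cohort(cohort_params(n = c(NC = 8L, MCI = 12L, AD = 8L),
                                      seed = 35L))
  oracle <- function(train_df, val_df) as.numeric(val_df$.target)
  dir <- withr::local_tempdir()
  run_experiment(ch, "score_regression", "M06",
                 train_cfg = train_config("score_regression", folds = 3L),
                 predictor = oracle, seed = 1L, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "config.json", "splits.csv", "fold_metrics.csv", "predictions.csv",
    "pooled_metrics.json"
  )))))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_identical(cfg$task, "score_regression")
})
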