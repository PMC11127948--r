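tiny_params <- function(...) {
  cohort_params(n = c(NC = 6L, MCI = 10L, AD = 5L), seed = 42L, ...)
}

test_that("default parameters produce the 138 + 238 + 111 cohort", {
  ch <- generate_cohort(cohort_params())
  expect_identical(nrow(ch), 487L)
  expect_equal(as.integer(table(factor(ch$group, c("NC", "MCI", "AD")))),
               c(138L, 238L, 111L))
})

test_that("generation is deterministic in the seed and sensitive to it", {
  a <- generate_cohort(tiny_params())
  b <- generate_cohort(tiny_params())
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(cohort_params(n = c(NC = 6L, MCI = 10L, AD = 5L),
                                      seed = 43L))
  expect_false(identical(a$severity, c2$severity))
})

test_that("an empty cohort is allowed and negative sizes are rejected", {
  ch <- generate_cohort(cohort_params(n = c(NC = 0L, MCI = 0L, AD = 0L)))
  expect_identical(nrow(ch), 0L)
  expect_true(all(c("id", "mmse_bl", "conv_m36") %in% names(ch)))
  expect_error(cohort_params(n = c(NC = -1L, MCI = 0L, AD = 0L)),
               "nonnegative")
})

test_that("scores respect their scales and severity ordering across groups", {
  ch <- generate_cohort(cohort_params(n = c(NC = 50L, MCI = 50L, AD = 50L),
                                      seed = 3L))
  expect_true(all(ch$mmse_bl >= 0 & ch$mmse_bl <= 30))
  expect_true(all(ch$adas11_bl >= 0 & ch$adas11_bl <= 70))
  long_cols <- grep("^(mmse|adas11)_m", names(ch), value = TRUE)
  for (cl in long_cols) {
    v <- ch[[cl]][!is.na(ch[[cl]])]
    hi <- if (startsWith(cl, "mmse")) 30 else 70
    expect_true(all(v >= 0 & v <= hi))
  }
  med <- tapply(ch$severity, ch$group, median)
  expect_true(med[["NC"]] < med[["MCI"]] && med[["MCI"]] < med[["AD"]])
})

test_that("conversion labels are monotone: pMCI persists at later horizons", {
  ch <- generate_cohort(cohort_params(n = c(NC = 0L, MCI = 400L, AD = 0L),
                                      seed = 5L,
                                      dropout = c(M06 = 1, M12 = 1,
                                                  M24 = 1, M36 = 1)))
  lab <- ch[, c("conv_m12", "conv_m24", "conv_m36")] == "pMCI"
  expect_false(any(lab[, 1] & !lab[, 2]))
  expect_false(any(lab[, 2] & !lab[, 3]))
})

test_that("progression is linear in time and boundary cases label as designed", {
  expect_equal(progression(2, 1, c(0, 6, 12, 24, 36)),
               c(2, 2.5, 3, 4, 5))
  expect_error(progression(1, 1, -6), "nonnegative")
  expect_error(progression(1, 1, 18), "one of")
  p <- cohort_params()
  # s0 at the threshold with any nonnegative rate: progressive at every horizon
  expect_true(all(progression(p$theta, 0.7, c(12, 24, 36)) >= p$theta))
  expect_true(all(progression(p$theta, 0, c(12, 24, 36)) >= p$theta))
})

test_that("zero progression rate keeps sub-threshold subjects stable at all horizons", {
  p <- cohort_params()
  s0 <- p$theta - 0.5
  expect_true(all(progression(s0, 0, c(12, 24, 36)) < p$theta))
})

test_that("the M36 progressive fraction matches its closed-form probability", {
  p <- cohort_params(n = c(NC = 0L, MCI = 4000L, AD = 0L), seed = 9L,
                     dropout = c(M06 = 1, M12 = 1, M24 = 1, M36 = 1))
  ch <- generate_cohort(p)
  frac <- mean(ch$conv_m36 == "pMCI")
  # P(s0 + 3 * rate >= theta) by numeric integration over the truncated
  # normals of s0 and rate
  f_s0 <- function(s) {
    dnorm(s, p$severity_mean[["MCI"]], p$severity_sd[["MCI"]]) /
      (pnorm(p$severity_scale, p$severity_mean[["MCI"]], p$severity_sd[["MCI"]]) -
         pnorm(0, p$severity_mean[["MCI"]], p$severity_sd[["MCI"]]))
  }
  p_rate_ge <- function(q) { # P(rate >= q) for rate ~ N(mu, sd) truncated at 0
    mu <- p$rate_mean[["MCI"]]
    tail_lo <- pnorm(0, mu, p$rate_sd)
    pmin(1, (1 - pnorm(pmax(q, 0), mu, p$rate_sd)) / (1 - tail_lo))
  }
  expected <- integrate(function(s) {
    f_s0(s) * p_rate_ge((p$theta - s) / 3)
  }, 0, p$severity_scale)$value
  mc_err <- 3 * sqrt(expected * (1 - expected) / nrow(ch))
  expect_lt(abs(frac - expected), mc_err + 0.01)
})

test_that("group means converge to the configured calibrated values at n = 10,000", {
  p <- cohort_params(n = c(NC = 10000L, MCI = 0L, AD = 10000L), seed = 17L)
  ch <- generate_cohort(p)
  for (g in c("NC", "AD")) {
    sub <- ch[ch$group == g, ]
    for (f in c("mmse_bl", "adas11_bl", "ravlt_imm_bl")) {
      target <- p$features$mean[p$features$group == g &
                                  p$features$feature == f]
      se <- sd(sub[[f]]) / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[f]]) - target), 3 * se + 1e-3)
    }
  }
})

test_that("volumes lose focal voxels monotonically with severity, exactly none at zero", {
  p <- cohort_params()
  v0 <- generate_volume(0, c(32L, 32L, 32L), p, seed = 1)
  expect_identical(v0$present_count, v0$baseline_count)
  counts <- vapply(c(0, 2, 4, 6, 8, 10), function(s) {
    generate_volume(s, c(32L, 32L, 32L), p, seed = 1)$present_count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[6], round(v0$baseline_count * (1 - p$beta)))
  expect_error(generate_volume(-1, c(32L, 32L, 32L), p), "nonnegative")
  expect_error(generate_volume(1, c(8L, 8L, 8L), p), "too small")
})

test_that("regressing measured sub-region volume on severity recovers the atrophy slope", {
  p <- cohort_params(seed = 21L)
  set.seed(21)
  s <- runif(200, 0, 10)
  counts <- vapply(seq_along(s), function(i) {
    generate_volume(s[i], c(32L, 32L, 32L), p, seed = i)$present_count
  }, numeric(1))
  b <- generate_volume(0, c(32L, 32L, 32L), p, seed = 1)$baseline_count
  slope <- coef(lm(counts ~ I(s / p$severity_scale)))[2]
  expect_lt(abs(slope - (-p$beta * b)) / (p$beta * b), 0.1)
})

test_that("a threshold count in the focal region recovers severity from the image alone", {
  p <- cohort_params(seed = 4L)
  ch <- generate_cohort(cohort_params(n = c(NC = 40L, MCI = 60L, AD = 30L),
                                      seed = 4L))
  feat <- vapply(seq_len(nrow(ch)), function(i) {
    v <- generate_volume(ch$severity[i], p$shape, p, seed = ch$volume_seed[i])
    subregion_bright_count(v)
  }, numeric(1))
  expect_gt(abs(cor(feat, ch$severity)), 0.8)
})

test_that("tabular features correlate with severity in the configured directions", {
  ch <- generate_cohort(cohort_params(n = c(NC = 0L, MCI = 2000L, AD = 0L),
                                      seed = 6L))
  expect_lt(cor(ch$mmse_bl, ch$severity), -0.3)
  expect_gt(cor(ch$adas11_bl, ch$severity), 0.3)
  expect_gt(cor(ch$ttau, log(ch$severity + 1)), 0.1)
  expect_true(all(ch$apoe4 %in% 0:2))
})

test_that("written cohorts round trip through CSV + NIfTI + manifest", {
  p <- tiny_params()
  ch <- generate_cohort(p)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(ch, dir, p)
  expect_identical(length(manifest$volumes), nrow(ch))
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back), as.data.frame(ch), tolerance = 1e-12,
               ignore_attr = TRUE)
  # volumes decode to the generated data
  v1 <- read_volume(file.path(dir, manifest$volumes[[ch$id[1]]]))
  ref <- generate_volume(ch$severity[1], p$shape, p, ch$volume_seed[1])$data
  expect_equal(as.numeric(v1), as.numeric(ref), tolerance = 1e-6)
})

test_that("writing the same seeded cohort twice is byte-identical", {
  p <- tiny_params()
  ch <- generate_cohort(p)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(ch, d1, p)
  write_cohort(ch, d2, p)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  f1 <- file.path(d1, "volumes", paste0(ch$id[1], ".nii.gz"))
  f2 <- file.path(d2, "volumes", paste0(ch$id[1], ".nii.gz"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("per-horizon target counts decline monotonically under default dropout", {
  ch <- generate_cohort(cohort_params(seed = 2L))
  counts <- vapply(c("mmse_m06", "mmse_m12", "mmse_m24", "mmse_m36"),
                   function(cl) sum(!is.na(ch[[cl]])), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # dropout is monotone per subject: observed at M24 implies observed at M12
  expect_false(any(!is.na(ch$mmse_m24) & is.na(ch$mmse_m12)))
})

test_that("an empty cohort writes a valid header-only CSV", {
  p <- cohort_params(n = c(NC = 0L, MCI = 0L, AD = 0L))
  ch <- generate_cohort(p)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir, p)
  lines <- readLines(file.path(dir, "cohort.csv"))
  expect_identical(length(lines), 1L)
  expect_identical(nrow(read_cohort(dir)), 0L)
})
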