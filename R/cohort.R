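# Synthetic ADNI-like cohort: a latent per-subject disease severity drives
# (i) a focal-atrophy signal in a phantom volume, (ii) correlated tabular
# features whose group-wise means are calibrated to a reference cohort
# description, and (iii) longitudinal score trajectories and conversion
# labels through a linear severity-progression model.

#' Default per-group tabular feature description
#'
#' Group means and standard deviations of the clinical scores and
#' demographics (normal controls / MCI / AD), with each feature's
#' correlation `lambda` to the latent severity and its valid range.
#' @return A tibble with one row per (feature, group).
#' @export
cohort_feature_table <- function() {
  tibble::tribble(
    ~feature,     ~group, ~mean,  ~sd,   ~lambda, ~lo, ~hi,
    "mmse_bl",     "NC",  28.99,  1.24,  -0.60,    0,   30,
    "mmse_bl",     "MCI", 28.19,  1.63,  -0.60,    0,   30,
    "mmse_bl",     "AD",  23.23,  2.04,  -0.60,    0,   30,
    "adas11_bl",   "NC",   5.93,  3.03,   0.65,    0,   70,
    "adas11_bl",   "MCI",  9.12,  4.26,   0.65,    0,   70,
    "adas11_bl",   "AD",  21.05,  7.00,   0.65,    0,   70,
    "cdrsb_bl",    "NC",   0.03,  0.14,   0.70,    0,   18,
    "cdrsb_bl",    "MCI",  1.39,  0.87,   0.70,    0,   18,
    "cdrsb_bl",    "AD",   4.59,  1.60,   0.70,    0,   18,
    "ravlt_imm_bl", "NC", 45.15,  9.99,  -0.60,    0,   75,
    "ravlt_imm_bl", "MCI", 37.02, 10.60, -0.60,    0,   75,
    "ravlt_imm_bl", "AD",  21.57,  6.99, -0.60,    0,   75,
    "age",         "NC",  73.98,  5.89,   0.10,   40,  110,
    "age",         "MCI", 75.18,  7.41,   0.10,   40,  110,
    "age",         "AD",  74.28,  8.41,   0.10,   40,  110,
    "education",   "NC",  16.47,  2.61,  -0.05,    0,   30,
    "education",   "MCI", 15.97,  2.59,  -0.05,    0,   30,
    "education",   "AD",  15.58,  2.63,  -0.05,    0,   30
  )
}

#' Names of the tabular feature vector, in canonical order
#'
#' Baseline clinical scores, genetics, then fluid biomarkers. This fixed
#' order is the tabular input contract of the fusion layer
#' (`tabular_dim = 8`).
#' @return Character vector of column names.
#' @export
tabular_features <- function() {
  c("mmse_bl", "adas11_bl", "cdrsb_bl", "ravlt_imm_bl",
    "apoe4", "abeta_ratio", "ttau", "ptau")
}

#' Cohort generator parameters
#'
#' Defaults emulate a reference clinical cohort: 138 normal controls, 238 MCI and
#' 111 AD subjects; per-group clinical-score means and SDs from the cohort
#' demographics table; a latent severity on a 0-10 scale (truncated normal
#' per group, overlapping); a fractional focal-atrophy effect `beta`; a
#' nonnegative yearly progression rate; a conversion threshold `theta`; and
#' per-horizon observation probabilities shaped like a real cohort's declining
#' follow-up counts.
#'
#' @param n Named group sizes `c(NC, MCI, AD)`.
#' @param shape Volume shape `(d, h, w)`; phantoms default to 32^3.
#' @param severity_mean,severity_sd Per-group latent severity distribution
#'   (truncated to `[0, severity_scale]`).
#' @param severity_scale Upper end of the severity scale; `s / scale`
#'   (clipped to `[0, 1]`) is the normalized severity driving atrophy.
#' @param beta Fractional focal sub-region volume lost at normalized
#'   severity 1 (`0 <= beta <= 1`).
#' @param noise_sd Additive Gaussian intensity noise in the phantom.
#' @param rate_mean,rate_sd Per-group yearly severity progression rate
#'   (truncated at 0 so severity never decreases).
#' @param theta Conversion threshold: an MCI subject is labelled
#'   progressive at horizon `t` iff `s(t) >= theta`.
#' @param traj_mmse_slope,traj_adas_slope Score change per severity unit in
#'   the longitudinal trajectories (MMSE falls, ADAS-11 rises).
#' @param score_noise_sd Noise SD of the longitudinal scores
#'   `c(mmse, adas11)`, in score points.
#' @param dropout Per-horizon observation probabilities
#'   `c(M06, M12, M24, M36)`, nonincreasing; dropout is monotone (a subject
#'   lost at one horizon stays lost).
#' @param features Feature description table (see [cohort_feature_table()]).
#' @param volume_format `"nii.gz"` or `"nii"` for [write_cohort()].
#' @param seed Seed making the whole cohort reproducible.
#' @return A `cohort_params` object.
#' @export
cohort_params <- function(n = c(NC = 138L, MCI = 238L, AD = 111L),
                          shape = c(32L, 32L, 32L),
                          severity_mean = c(NC = 1, MCI = 3, AD = 6),
                          severity_sd = c(NC = 0.8, MCI = 1.2, AD = 1.5),
                          severity_scale = 10,
                          beta = 0.4,
                          noise_sd = 0.1,
                          rate_mean = c(NC = 0.05, MCI = 0.5, AD = 0.7),
                          rate_sd = 0.2,
                          theta = 4.5,
                          traj_mmse_slope = 1.5,
                          traj_adas_slope = 2.5,
                          score_noise_sd = c(mmse = 1.0, adas11 = 2.0),
                          dropout = c(M06 = 0.94, M12 = 0.90,
                                      M24 = 0.73, M36 = 0.41),
                          features = cohort_feature_table(),
                          volume_format = c("nii.gz", "nii"),
                          seed = 1L) {
  if (length(n) != 3L) abort("`n` must give three group sizes (NC, MCI, AD)")
  if (is.null(names(n))) names(n) <- c("NC", "MCI", "AD")
  if (any(n < 0) || any(n != as.integer(n))) {
    abort("group sizes must be nonnegative integers")
  }
  if (any(severity_sd <= 0) || rate_sd <= 0) abort("SDs must be positive")
  if (beta < 0 || beta > 1) abort("`beta` must lie in [0, 1]")
  if (any(diff(dropout) > 0)) abort("`dropout` probabilities must be nonincreasing")
  structure(list(
    n = setNames(as.integer(n), c("NC", "MCI", "AD")),
    shape = check_positive_int(shape, "shape"),
    severity_mean = severity_mean, severity_sd = severity_sd,
    severity_scale = severity_scale,
    beta = beta, noise_sd = noise_sd,
    rate_mean = rate_mean, rate_sd = rate_sd, theta = theta,
    traj_mmse_slope = traj_mmse_slope, traj_adas_slope = traj_adas_slope,
    score_noise_sd = score_noise_sd,
    dropout = dropout,
    features = features,
    biomarkers = list(
      abeta_ratio = c(mu0 = log(0.07), slope = -0.45, sdlog = 0.25),
      ttau = c(mu0 = log(280), slope = 0.35, sdlog = 0.30),
      ptau = c(mu0 = log(26), slope = 0.40, sdlog = 0.30)
    ),
    apoe = c(slope = 0.45, cut1 = -0.2, cut2 = 2.2),
    sex_male_prob = c(NC = 69 / 138, MCI = 137 / 238, AD = 67 / 111),
    volume_format = match.arg(volume_format),
    seed = seed
  ), class = "cohort_params")
}

# Truncated-normal helpers (inverse-CDF sampling; closed-form moments).
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

tnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# E[clip(X, lo, hi)] for X ~ N(m, s), closed form.
clipped_normal_mean <- function(m, s, lo, hi) {
  if (s <= 0) return(pmin(pmax(m, lo), hi))
  a <- (lo - m) / s
  b <- (hi - m) / s
  lo * pnorm(a) + hi * (1 - pnorm(b)) + m * (pnorm(b) - pnorm(a)) -
    s * (dnorm(b) - dnorm(a))
}

# Location calibration: clinical scores live on bounded scales, and the
# configured group means are means of the *bounded* values. Solve for the
# pre-clip location so that after mixing with the (standardized truncated
# normal) severity and clipping, the expected value equals the target mean.
calibrate_location <- function(target, sigma, lambda, lo, hi, sev) {
  if (min(target - lo, hi - target) > 4 * sigma) return(target)
  smom <- tnorm_moments(sev$mean, sev$sd, sev$lo, sev$hi)
  zlo <- (sev$lo - smom["mean"]) / smom["sd"]
  zhi <- (sev$hi - smom["mean"]) / smom["sd"]
  # density of standardized truncated severity
  zmass <- pnorm(sev$hi, sev$mean, sev$sd) - pnorm(sev$lo, sev$mean, sev$sd)
  fz <- function(z) {
    s <- smom["mean"] + smom["sd"] * z
    dnorm(s, sev$mean, sev$sd) * smom["sd"] / zmass
  }
  resid_sd <- sigma * sqrt(max(1 - lambda^2, 0))
  expected <- function(mu) {
    integrate(function(z) {
      fz(z) * clipped_normal_mean(mu + sigma * lambda * z, resid_sd, lo, hi)
    }, zlo, zhi, rel.tol = 1e-9)$value
  }
  uniroot(function(mu) expected(mu) - target,
          lower = lo - 10 * sigma - abs(target),
          upper = hi + 10 * sigma + abs(target),
          tol = 1e-9)$root
}

#' Severity progression
#'
#' Severity advances linearly in time: `s(t) = s0 + rate * t / 12` with `t`
#' in months. Longitudinal scores and conversion labels in
#' [generate_cohort()] derive from this trajectory (progressive MCI at
#' horizon `t` iff `s(t) >= theta`).
#'
#' @param s0 Baseline severity (vector).
#' @param rate Yearly progression rate (nonnegative; recycled).
#' @param months Months since baseline; one of 0, 6, 12, 24, 36.
#' @return Severity at `months`.
#' @export
progression <- function(s0, rate, months) {
  if (any(months < 0)) abort("`months` must be nonnegative")
  if (!all(months %in% c(0, 6, 12, 24, 36))) {
    abort("`months` must be one of 0, 6, 12, 24, 36")
  }
  s0 + rate * months / 12
}

#' Generate a synthetic cohort
#'
#' Draws per-subject latent severities (per-group truncated normals with
#' deliberate overlap), derives the calibrated tabular features, biomarker
#' and genetic features, longitudinal MMSE/ADAS-11 scores at months 6, 12,
#' 24 and 36, and conversion labels for the MCI group at months 12, 24 and
#' 36, with monotone dropout shaping the per-horizon availability. Fully
#' reproducible from `params$seed`.
#'
#' @param params A [cohort_params()].
#' @return A tibble with one row per subject (the cohort table); the
#'   generating parameters are attached as attribute `"cohort_params"`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) abort("`params` must be cohort_params")
  groups <- c("NC", "MCI", "AD")
  ntot <- sum(params$n)
  empty <- cohort_skeleton()
  if (ntot == 0L) {
    attr(empty, "cohort_params") <- params
    return(empty)
  }
  with_seed(params$seed, {
    rows <- lapply(groups, function(g) {
      ng <- params$n[[g]]
      if (ng == 0L) return(NULL)
      sev <- list(mean = params$severity_mean[[g]],
                  sd = params$severity_sd[[g]],
                  lo = 0, hi = params$severity_scale)
      s <- rtnorm(ng, sev$mean, sev$sd, sev$lo, sev$hi)
      smom <- tnorm_moments(sev$mean, sev$sd, sev$lo, sev$hi)
      zs <- (s - smom["mean"]) / smom["sd"]
      tab <- list()
      feats <- params$features[params$features$group == g, ]
      for (i in seq_len(nrow(feats))) {
        fr <- feats[i, ]
        mu <- calibrate_location(fr$mean, fr$sd, fr$lambda, fr$lo, fr$hi, sev)
        pre <- mu + fr$sd * (fr$lambda * zs +
                               sqrt(1 - fr$lambda^2) * rnorm(ng))
        tab[[fr$feature]] <- pmin(pmax(pre, fr$lo), fr$hi)
      }
      # genetics: ApoE4 allele count via an ordered-logit link on severity
      eta <- params$apoe[["slope"]] * (s - 3)
      p_ge1 <- stats::plogis(eta - params$apoe[["cut1"]])
      p_2 <- stats::plogis(eta - params$apoe[["cut2"]])
      u <- runif(ng)
      apoe4 <- as.integer(u < p_2) + as.integer(u < p_ge1)
      # fluid biomarkers: lognormal with severity-linked location
      bio <- lapply(params$biomarkers, function(bm) {
        exp(bm[["mu0"]] + bm[["slope"]] * (s - 3) / 3 +
              bm[["sdlog"]] * rnorm(ng))
      })
      rate <- rtnorm(ng, params$rate_mean[[g]], params$rate_sd, lo = 0)
      sex <- ifelse(runif(ng) < params$sex_male_prob[[g]], "M", "F")
      u_drop <- runif(ng)
      tibble::tibble(
        group = g, severity = s, rate = rate, sex = sex,
        age = tab$age, education = tab$education,
        mmse_bl = tab$mmse_bl, adas11_bl = tab$adas11_bl,
        cdrsb_bl = tab$cdrsb_bl, ravlt_imm_bl = tab$ravlt_imm_bl,
        apoe4 = apoe4,
        abeta_ratio = bio$abeta_ratio, ttau = bio$ttau, ptau = bio$ptau,
        u_drop = u_drop
      )
    })
    df <- dplyr::bind_rows(rows)
    df$id <- sprintf("S%04d", seq_len(nrow(df)))
    df$volume_seed <- sample.int(.Machine$integer.max - 1L, nrow(df))
    horizons <- c(M06 = 6, M12 = 12, M24 = 24, M36 = 36)
    for (h in names(horizons)) {
      m <- horizons[[h]]
      st <- progression(df$severity, df$rate, m)
      ds <- st - df$severity
      observed <- df$u_drop <= params$dropout[[h]]
      mmse <- pmin(pmax(df$mmse_bl - params$traj_mmse_slope * ds +
                          rnorm(nrow(df), sd = params$score_noise_sd[["mmse"]]),
                        0), 30)
      adas <- pmin(pmax(df$adas11_bl + params$traj_adas_slope * ds +
                          rnorm(nrow(df), sd = params$score_noise_sd[["adas11"]]),
                        0), 70)
      df[[paste0("mmse_", tolower(h))]] <- ifelse(observed, mmse, NA_real_)
      df[[paste0("adas11_", tolower(h))]] <- ifelse(observed, adas, NA_real_)
      if (m >= 12) {
        conv <- ifelse(st >= params$theta, "pMCI", "sMCI")
        conv[df$group != "MCI"] <- NA_character_
        conv[!observed] <- NA_character_
        df[[paste0("conv_", tolower(h))]] <- conv
      }
    }
    df$u_drop <- NULL
    df <- df[, names(empty)]
    attr(df, "cohort_params") <- params
    df
  })
}

cohort_skeleton <- function() {
  tibble::tibble(
    id = character(), group = character(), severity = numeric(),
    rate = numeric(), sex = character(), age = numeric(),
    education = numeric(),
    mmse_bl = numeric(), adas11_bl = numeric(), cdrsb_bl = numeric(),
    ravlt_imm_bl = numeric(), apoe4 = integer(), abeta_ratio = numeric(),
    ttau = numeric(), ptau = numeric(),
    mmse_m06 = numeric(), adas11_m06 = numeric(),
    mmse_m12 = numeric(), adas11_m12 = numeric(), conv_m12 = character(),
    mmse_m24 = numeric(), adas11_m24 = numeric(), conv_m24 = character(),
    mmse_m36 = numeric(), adas11_m36 = numeric(), conv_m36 = character(),
    volume_seed = integer()
  )
}

#' Generate one phantom volume with severity-linked focal atrophy
#'
#' Builds an ellipsoidal "brain" of tissue-like intensity bands (background
#' 0.02, tissue 0.75, a central fluid-filled cavity 0.25) containing a
#' designated bright focal sub-region (two small spheres standing in for
#' the medial-temporal structures that atrophy early). The sub-region
#' retains `round(baseline * (1 - beta * s_norm))` voxels, shed from its
#' rim outward cells becoming fluid-dark, so higher severity means a
#' strictly smaller sub-region. Additive Gaussian noise is applied last.
#'
#' @param s Severity (`s >= 0`).
#' @param shape Volume shape `(d, h, w)`; each extent must be at least 16.
#' @param params A [cohort_params()] (for `beta`, `noise_sd`,
#'   `severity_scale`).
#' @param seed Per-subject seed.
#' @return A list: `data` (3-axis array), `baseline_mask` (logical array of
#'   the sub-region at severity 0), `baseline_count`, `present_count`.
#' @export
generate_volume <- function(s, shape = NULL, params = cohort_params(),
                            seed = 1L) {
  if (s < 0) abort("severity must be nonnegative")
  shape <- check_positive_int(shape %||% params$shape, "shape")
  if (length(shape) != 3L) abort("`shape` must have length 3")
  if (any(shape < 16L)) {
    abort("shape too small to contain the focal sub-region (min extent 16)")
  }
  ctr <- (shape + 1) / 2
  ax <- 0.42 * shape
  d <- seq_len(shape[1])
  h <- seq_len(shape[2])
  w <- seq_len(shape[3])
  dd <- ((d - ctr[1]) / ax[1])^2
  hh <- ((h - ctr[2]) / ax[2])^2
  ww <- ((w - ctr[3]) / ax[3])^2
  e2 <- outer(outer(dd, hh, "+"), ww, "+")
  vol <- array(0.02, dim = shape)
  vol[e2 <= 1] <- 0.75
  vent <- outer(outer(((d - ctr[1]) / (0.12 * shape[1]))^2,
                      ((h - ctr[2]) / (0.12 * shape[2]))^2, "+"),
                ((w - ctr[3]) / (0.18 * shape[3]))^2, "+")
  vol[vent <= 1] <- 0.25
  # focal sub-region: two lateral spheres below the midline
  r0 <- 0.09 * min(shape)
  cds <- list(ctr + c(0.12, 0.22, 0) * shape,
              ctr + c(0.12, -0.22, 0) * shape)
  idx <- integer(0)
  dist <- numeric(0)
  for (cc in cds) {
    d2 <- outer(outer((d - cc[1])^2, (h - cc[2])^2, "+"), (w - cc[3])^2, "+")
    inside <- which(d2 <= r0^2 & e2 <= 1)
    idx <- c(idx, inside)
    dist <- c(dist, sqrt(d2[inside]))
  }
  dup <- duplicated(idx)
  idx <- idx[!dup]
  dist <- dist[!dup]
  if (length(idx) < 8L) abort("shape too small to contain the focal sub-region")
  baseline_mask <- array(FALSE, dim = shape)
  baseline_mask[idx] <- TRUE
  b <- length(idx)
  s_norm <- pmin(pmax(s / params$severity_scale, 0), 1)
  keep_n <- as.integer(round(b * (1 - params$beta * s_norm)))
  ord <- order(dist, idx)
  keep <- idx[ord][seq_len(keep_n)]
  lost <- setdiff(idx, keep)
  vol[keep] <- 1.0
  vol[lost] <- 0.25
  with_seed(seed, {
    vol <- vol + array(rnorm(prod(shape), sd = params$noise_sd), dim = shape)
  })
  list(data = vol, baseline_mask = baseline_mask,
       baseline_count = b, present_count = keep_n)
}

#' A simple image-side severity readout
#'
#' Counts bright voxels (intensity above `thr`) inside the baseline focal
#' sub-region: a one-number feature that tracks the latent severity and
#' verifies that generated volumes carry learnable signal.
#'
#' @param vol A generated volume list (from [generate_volume()]) or a
#'   3-axis array plus a `mask`.
#' @param mask Logical array (defaults to the generated baseline mask).
#' @param thr Intensity threshold (default 0.875, between tissue and the
#'   bright sub-region).
#' @return Integer voxel count.
#' @export
subregion_bright_count <- function(vol, mask = NULL, thr = 0.875) {
  if (is.list(vol) && !is.null(vol$data)) {
    mask <- mask %||% vol$baseline_mask
    vol <- vol$data
  }
  if (is.null(mask)) abort("`mask` is required when `vol` is a bare array")
  sum(vol[mask] > thr)
}

#' Write a cohort to disk
#'
#' Volumes as NIfTI (one file per subject, identity affine at 1 mm
#' isotropic), the cohort table as a single CSV (missing targets as empty
#' cells), and a JSON manifest linking subject ids to volume paths.
#'
#' @param records Cohort tibble from [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param params The generating [cohort_params()]; defaults to the ones
#'   attached to `records`.
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(records, out_dir,
                         params = attr(records, "cohort_params")) {
  if (is.null(params)) abort("`params` are required (attach or pass them)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vdir <- file.path(out_dir, "volumes")
  dir.create(vdir, showWarnings = FALSE)
  ext <- paste0(".", params$volume_format)
  paths <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    v <- generate_volume(records$severity[i], params$shape, params,
                         seed = records$volume_seed[i])
    paths[i] <- file.path("volumes", paste0(records$id[i], ext))
    write_volume(v$data, file.path(out_dir, paths[i]))
  }
  readr::write_csv(records, file.path(out_dir, "cohort.csv"), na = "")
  manifest <- list(
    n = as.list(table(factor(records$group, levels = c("NC", "MCI", "AD")))),
    shape = params$shape,
    seed = params$seed,
    cohort_table = "cohort.csv",
    volumes = as.list(setNames(paths, records$id))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a written cohort back
#'
#' @param dir Directory produced by [write_cohort()].
#' @return The cohort tibble, with the manifest attached as attribute
#'   `"manifest"`.
#' @export
read_cohort <- function(dir) {
  sk <- cohort_skeleton()
  df <- readr::read_csv(
    file.path(dir, "cohort.csv"),
    col_types = paste(vapply(sk, function(col) {
      if (is.character(col)) "c" else if (is.integer(col)) "i" else "d"
    }, character(1)), collapse = ""),
    na = "", show_col_types = FALSE
  )
  attr(df, "manifest") <- jsonlite::read_json(file.path(dir, "manifest.json"))
  df
}

#' Extract the tabular feature matrix
#'
#' @param cohort A cohort tibble.
#' @return Numeric matrix with columns in [tabular_features()] order.
#' @export
tabular_matrix <- function(cohort) {
  as.matrix(cohort[, tabular_features()])
}
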