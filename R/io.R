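#' Read / write a single-channel NIfTI volume
#'
#' Round trips are lossless for data and affine. Only three-axis
#' (single-channel) images are accepted; higher-rank files are rejected
#' with a message naming the extra axis.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a 3-axis numeric array with the affine
#'   attached as attribute `"affine"`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such volume file: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf(
                    "malformed NIfTI file '%s': %s", path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 3L) {
    abort(sprintf(
      "expected a single-channel 3-axis volume, got %d axes (extra axis %d has extent %d)",
      length(d), length(d), d[length(d)]))
  }
  out <- array(as.numeric(img), dim = d)
  attr(out, "affine") <- structure(as.matrix(RNifti::xform(img)),
                                   dimnames = NULL)
  out
}

#' @rdname read_volume
#' @param v A 3-axis numeric array (an attached `"affine"` attribute is
#'   honoured; the default is the identity at 1 mm isotropic).
#' @export
write_volume <- function(v, path) {
  if (length(dim(v)) != 3L) {
    abort(sprintf("volumes are written as 3-axis arrays, got %d axes",
                  length(dim(v))))
  }
  if (any(!is.finite(v))) abort("volumes must contain finite values only")
  aff <- attr(v, "affine") %||% diag(c(-1, -1, 1, 1)) # RAS identity, 1 mm
  img <- RNifti::asNifti(array(as.numeric(v), dim = dim(v)))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Image-enhancement configuration
#'
#' The in-scope intensity enhancement pipeline: histogram equalization over
#' brain-mask voxels towards a uniform target CDF, isotropic Gaussian
#' spatial smoothing, and a monotone nonlinear rescale (gamma). Each stage
#' is independently toggleable; the reference preprocessing names the three
#' stage families without parameters, so the defaults here are the simplest
#' member of each (256 equalization bins, sigma 0.5 voxel, gamma 1).
#'
#' @param equalize Apply histogram equalization?
#' @param bins Number of equalization bins.
#' @param sigma Gaussian smoothing SD in voxels (0 disables smoothing).
#' @param gamma Exponent of the monotone nonlinear rescale (1 disables).
#' @param mask `NULL` (all voxels), a scalar intensity threshold, or a
#'   logical array marking brain voxels; equalization statistics come from
#'   masked voxels only.
#' @return An `enhance_config` object.
#' @export
enhance_config <- function(equalize = TRUE, bins = 256L, sigma = 0.5,
                           gamma = 1, mask = NULL) {
  if (sigma < 0) abort("`sigma` must be nonnegative")
  if (gamma <= 0) abort("`gamma` must be positive")
  structure(list(equalize = isTRUE(equalize),
                 bins = check_positive_int(bins, "bins", min = 2L),
                 sigma = sigma, gamma = gamma, mask = mask),
            class = "enhance_config")
}

#' Enhance a volume's intensities
#'
#' Applies the stages of [enhance_config()] in order (equalization,
#' smoothing, gamma) and rescales the result to `[0, 1]`. A constant image
#' passes through unchanged: equalization of a degenerate histogram is
#' defined as the identity and the final rescale leaves a zero-range image
#' untouched (no division by zero).
#'
#' @param v A numeric array (any rank; operates on intensities).
#' @param config An [enhance_config()].
#' @return The enhanced array, same shape, values in `[0, 1]` (unless the
#'   input was constant).
#' @export
enhance_image <- function(v, config = enhance_config()) {
  if (any(!is.finite(v))) abort("volume must be finite")
  if (diff(range(v)) == 0) return(v) # constant image: identity, documented
  if (config$equalize) v <- hist_equalize(v, config$bins, config$mask)
  if (config$sigma > 0) v <- gauss_smooth(v, config$sigma)
  if (config$gamma != 1) v <- rescale01(v)^config$gamma
  rescale01(v)
}

rescale01 <- function(v) {
  rng <- range(v)
  span <- rng[2] - rng[1]
  # a numerically constant image stays untouched: rescaling would only
  # amplify floating-point dust
  if (span <= 1e-10 * max(1, abs(rng[1]), abs(rng[2]))) return(v)
  (v - rng[1]) / span
}

hist_equalize <- function(v, bins, mask = NULL) {
  msk <- if (is.null(mask)) {
    rep(TRUE, length(v))
  } else if (is.logical(mask)) {
    as.logical(mask)
  } else {
    as.numeric(v) > mask
  }
  vals <- as.numeric(v)[msk]
  if (!length(vals) || diff(range(vals)) == 0) return(v) # degenerate: identity
  rng <- range(vals)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(vals, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  cdf <- cumsum(cnt) / sum(cnt)
  # map every voxel (clamped into the mask range) through the bin CDF
  vi <- findInterval(pmin(pmax(as.numeric(v), rng[1]), rng[2]), brk,
                     rightmost.closed = TRUE, all.inside = TRUE)
  out <- cdf[vi]
  dim(out) <- dim(v)
  out
}

# Separable Gaussian smoothing; truncated kernels are renormalized at the
# boundary so constants are preserved exactly.
gauss_smooth <- function(v, sigma) {
  d <- dim(v)
  if (is.null(d)) d <- length(v)
  rad <- max(1L, ceiling(3 * sigma))
  smooth_axis <- function(x, axis) {
    n <- dim(x)[axis]
    K <- outer(seq_len(n), seq_len(n), function(i, j) {
      ifelse(abs(i - j) <= rad, dnorm(i - j, sd = sigma), 0)
    })
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(seq_along(dim(x)), axis))
    xp <- aperm(x, perm)
    m <- matrix(xp, nrow = n)
    yp <- array(K %*% m, dim = dim(xp))
    aperm(yp, order(perm))
  }
  out <- v
  for (a in seq_along(d)) out <- smooth_axis(out, a)
  out
}

#' Z-score tabular features with fold statistics
#'
#' Standardizes the feature columns using means and (sample) standard
#' deviations computed from the supplied table — or, when `stats` is
#' given, using those previously computed statistics, so held-out folds are
#' normalized with training-fold statistics only and no information leaks.
#' Missing values stay missing. A zero-variance feature gets a unit divisor
#' with a warning.
#'
#' @param table Cohort tibble (or any data frame with the feature columns).
#' @param stats Optional statistics tibble from a previous call.
#' @param features Feature columns to standardize (default
#'   [tabular_features()]).
#' @return A list with `data` (the standardized table) and `stats`
#'   (tibble of `feature`, `mean`, `sd`).
#' @export
normalize_tabular <- function(table, stats = NULL,
                              features = tabular_features()) {
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols)) {
    abort(sprintf("missing feature columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (is.null(stats)) {
    stats <- tibble::tibble(
      feature = features,
      mean = vapply(features, function(f) {
        mean(table[[f]], na.rm = TRUE)
      }, numeric(1)),
      sd = vapply(features, function(f) sd(table[[f]], na.rm = TRUE),
                  numeric(1))
    )
    bad <- !is.finite(stats$sd) | stats$sd == 0
    if (any(bad)) {
      warn(sprintf("zero-variance feature(s) %s: using unit divisor",
                   paste(stats$feature[bad], collapse = ", ")))
      stats$sd[bad] <- 1
    }
  }
  for (i in seq_len(nrow(stats))) {
    f <- stats$feature[i]
    table[[f]] <- (table[[f]] - stats$mean[i]) / stats$sd[i]
  }
  list(data = table, stats = stats)
}

#' Invert [normalize_tabular()]
#' @param table Standardized table.
#' @param stats Statistics tibble returned by [normalize_tabular()].
#' @return The table on the original scale.
#' @export
denormalize_tabular <- function(table, stats) {
  for (i in seq_len(nrow(stats))) {
    f <- stats$feature[i]
    table[[f]] <- table[[f]] * stats$sd[i] + stats$mean[i]
  }
  table
}
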