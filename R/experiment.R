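# The two study tasks as reproducible cross-validated runs, plus the
# ablation harness that re-runs a task under each architecture variant on
# identical folds.

horizons_for <- function(task) {
  if (task == "score_regression") c("M06", "M12", "M24", "M36")
  else c("M12", "M24", "M36")
}

target_column <- function(task, horizon, score) {
  horizon <- toupper(horizon)
  if (!horizon %in% horizons_for(task)) {
    abort(sprintf("horizon %s is not valid for %s (valid: %s)", horizon,
                  task, paste(horizons_for(task), collapse = ", ")))
  }
  if (task == "score_regression") {
    score <- match.arg(toupper(score), c("MMSE", "ADAS11"))
    paste0(if (score == "MMSE") "mmse_" else "adas11_", tolower(horizon))
  } else {
    paste0("conv_", tolower(horizon))
  }
}

#' Run one cross-validated prediction experiment
#'
#' Executes a task (per-horizon clinical-score regression, or MCI-to-AD
#' conversion classification) under repeated (stratified) k-fold
#' cross-validation: subjects lacking the horizon's target are excluded,
#' tabular features are z-scored with training-fold statistics only, a
#' fresh network is trained per fold, and metrics are computed on the
#' validation folds — both per fold and pooled over all validation
#' predictions.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (or [read_cohort()]).
#' @param task `"score_regression"` or `"conversion_classification"`.
#' @param horizon `"M06"`, `"M12"`, `"M24"` or `"M36"` (regression);
#'   `"M12"`, `"M24"` or `"M36"` (classification).
#' @param score `"MMSE"` or `"ADAS11"` (regression only).
#' @param model_cfg A [model_config()]; its task is overridden to `task`.
#' @param train_cfg A [train_config()]; its defaults follow the task.
#' @param params The [cohort_params()] used to generate volumes (defaults
#'   to the ones attached to `cohort`).
#' @param volumes Optional named list of precomputed (enhanced) volumes by
#'   subject id; generated on the fly otherwise.
#' @param enhance An [enhance_config()] applied to generated volumes, or
#'   `NULL` to skip enhancement.
#' @param predictor Optional function `(train_df, val_df) -> predictions`
#'   replacing the network (both data frames carry normalized features and
#'   a `.target` column); used to validate the harness itself against
#'   reference predictors.
#' @param calibrate Classification only: refit the probability scale of
#'   each fold's scores by a logistic (Platt) recalibration estimated on
#'   the training fold. The transform is monotone, so per-fold ranking
#'   metrics are unchanged; it aligns the probability scales of the fold
#'   models so that pooled ROC statistics mix comparable scores. Default
#'   `TRUE`.
#' @param seed Master seed (folds, weight init, batch order).
#' @param out_dir Optional run directory: configs, splits, metrics and
#'   predictions are written there as JSON/CSV.
#' @param verbose Print per-epoch losses.
#' @return An `mfsedrn_run` object; see [tidy.mfsedrn_run()] and
#'   [glance.mfsedrn_run()].
#' @export
run_experiment <- function(cohort, task = c("score_regression",
                                            "conversion_classification"),
                           horizon, score = "MMSE",
                           model_cfg = NULL, train_cfg = NULL,
                           params = attr(cohort, "cohort_params"),
                           volumes = NULL, enhance = enhance_config(),
                           predictor = NULL, seed = 1L, out_dir = NULL,
                           calibrate = TRUE, verbose = FALSE) {
  task <- match.arg(task)
  tcol <- target_column(task, horizon, score)
  df <- cohort[!is.na(cohort[[tcol]]), , drop = FALSE]
  if (task == "conversion_classification") {
    df <- df[df$group == "MCI", , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    abort(sprintf("no subjects with an observed %s target", tcol))
  }
  df$.target <- df[[tcol]]
  classification <- task == "conversion_classification"
  model_cfg <- model_cfg %||% model_config()
  model_cfg$task <- task
  train_cfg <- train_cfg %||% train_config(task)
  if (train_cfg$task != task) abort("train_cfg task must match `task`")

  labels <- if (classification) df$.target else NULL
  folds <- make_folds(df$id, labels = labels, folds = train_cfg$folds,
                      repeats = train_cfg$repeats, seed = seed)
  split_hash <- hash(folds[, c("repeat_idx", "fold", "val")])

  if (is.null(volumes) && is.null(predictor)) {
    if (is.null(params)) {
      abort("`params` needed to generate volumes (attach cohort_params or pass volumes)")
    }
    volumes <- prepare_volumes(df, params, enhance)
  }

  fold_rows <- list()
  pred_rows <- list()
  histories <- list()
  for (r in seq_len(nrow(folds))) {
    tr_ids <- folds$train[[r]]
    va_ids <- folds$val[[r]]
    tr <- df[match(tr_ids, df$id), , drop = FALSE]
    va <- df[match(va_ids, df$id), , drop = FALSE]
    norm <- normalize_tabular(tr)
    va_n <- normalize_tabular(va, stats = norm$stats)$data
    tr_n <- norm$data
    if (!is.null(predictor)) {
      preds <- predictor(tr_n, va_n)
    } else {
      fold_seed <- child_seed(seed, "fold", folds$repeat_idx[r], folds$fold[r])
      model <- build_model(model_cfg, seed = fold_seed)
      ytr <- if (classification) as_binary_labels(tr$.target) else tr$.target
      tabtr <- if (model_cfg$no_fusion) NULL else tabular_matrix(tr_n)
      tabva <- if (model_cfg$no_fusion) NULL else tabular_matrix(va_n)
      fold_tc <- train_cfg
      fold_tc$seed <- fold_seed
      fit <- train(model, list(x = volumes[tr_ids], tab = tabtr, y = ytr),
                   fold_tc, verbose = verbose)
      histories[[r]] <- fit$history
      preds <- predict(fit$model, volumes[va_ids], tabva)
      if (classification && isTRUE(calibrate)) {
        tr_preds <- predict(fit$model, volumes[tr_ids], tabtr)
        preds <- platt_recalibrate(tr_preds, ytr, preds)
      }
    }
    obs <- va$.target
    pred_rows[[r]] <- tibble::tibble(
      repeat_idx = folds$repeat_idx[r], fold = folds$fold[r], id = va_ids,
      observed = as.character(obs), predicted = as.numeric(preds)
    )
    fold_rows[[r]] <- fold_metric_row(obs, preds, classification,
                                      folds$repeat_idx[r], folds$fold[r])
  }
  predictions <- dplyr::bind_rows(pred_rows)
  metrics <- dplyr::bind_rows(fold_rows)
  pooled <- pooled_metrics(predictions, classification)
  run <- structure(list(
    task = task, horizon = toupper(horizon),
    score = if (classification) NA_character_ else toupper(score),
    n = nrow(df), folds = folds, split_hash = split_hash,
    metrics = metrics, pooled = pooled, predictions = predictions,
    histories = histories,
    model_cfg = model_cfg, train_cfg = train_cfg, seed = seed
  ), class = "mfsedrn_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Monotone logistic rescaling of classification scores, fitted on the
# training fold only; degenerate fits fall back to the raw scores.
platt_recalibrate <- function(train_scores, train_labels, val_scores) {
  if (length(unique(train_labels)) < 2L || sd(train_scores) < 1e-12) {
    return(val_scores)
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm(train_labels ~ train_scores,
                                family = stats::binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !all(is.finite(coef(fit)))) return(val_scores)
  as.numeric(stats::predict(fit, newdata = data.frame(train_scores = val_scores),
                            type = "response"))
}

prepare_volumes <- function(df, params, enhance) {
  vols <- vector("list", nrow(df))
  names(vols) <- df$id
  for (i in seq_len(nrow(df))) {
    v <- generate_volume(df$severity[i], params$shape, params,
                         seed = df$volume_seed[i])$data
    if (!is.null(enhance)) v <- enhance_image(v, enhance)
    vols[[i]] <- v
  }
  vols
}

fold_metric_row <- function(obs, preds, classification, repeat_idx, fold) {
  if (classification) {
    lab <- as_binary_labels(obs)
    cm <- classification_metrics(lab, preds)
    auc <- if (length(unique(lab)) == 2L) roc_auc(lab, preds)$auc else NA_real_
    tibble::tibble(repeat_idx = repeat_idx, fold = fold, n = length(obs),
                   acc = cm$acc, pre = cm$pre, rec = cm$rec, f1 = cm$f1,
                   auc = auc)
  } else {
    tibble::tibble(repeat_idx = repeat_idx, fold = fold, n = length(obs),
                   rmse = rmse(obs, preds), mae = mae(obs, preds))
  }
}

pooled_metrics <- function(predictions, classification) {
  if (classification) {
    lab <- as_binary_labels(predictions$observed)
    cm <- classification_metrics(lab, predictions$predicted)
    ra <- roc_auc(lab, predictions$predicted)
    tibble::tibble(n = nrow(predictions), acc = cm$acc, pre = cm$pre,
                   rec = cm$rec, f1 = cm$f1, auc = ra$auc)
  } else {
    obs <- as.numeric(predictions$observed)
    tibble::tibble(n = nrow(predictions),
                   rmse = rmse(obs, predictions$predicted),
                   mae = mae(obs, predictions$predicted))
  }
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(task = run$task, horizon = run$horizon, score = run$score,
              seed = run$seed, split_hash = run$split_hash,
              model = unclass(run$model_cfg), train = unclass(run$train_cfg))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  splits <- run$folds
  splits$train <- vapply(splits$train, paste, "", collapse = ";")
  splits$val <- vapply(splits$val, paste, "", collapse = ";")
  readr::write_csv(splits, file.path(out_dir, "splits.csv"))
  readr::write_csv(run$metrics, file.path(out_dir, "fold_metrics.csv"))
  readr::write_csv(run$predictions, file.path(out_dir, "predictions.csv"))
  jsonlite::write_json(as.list(run$pooled),
                       file.path(out_dir, "pooled_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the ablation suite
#'
#' Repeats one experiment under the five ablation variants plus the full
#' model, on identical folds and fold seeds (the controlled comparison of
#' the ablation design), and assembles a report table with one row per
#' group.
#'
#' @inheritParams run_experiment
#' @param groups Ablation groups to run (default all six, in report order).
#' @return An `mfsedrn_ablation` tibble: one row per group with the pooled
#'   metrics and the shared fold-split hash; individual runs are attached
#'   as attribute `"runs"`.
#' @export
run_ablation_suite <- function(cohort, task = c("score_regression",
                                                "conversion_classification"),
                               horizon, score = "MMSE",
                               model_cfg = NULL, train_cfg = NULL,
                               params = attr(cohort, "cohort_params"),
                               volumes = NULL, enhance = enhance_config(),
                               seed = 1L, groups = ablation_groups(),
                               verbose = FALSE) {
  task <- match.arg(task)
  model_cfg <- model_cfg %||% model_config()
  model_cfg$task <- task
  if (is.null(volumes)) {
    tcol <- target_column(task, horizon, score)
    df <- cohort[!is.na(cohort[[tcol]]), , drop = FALSE]
    if (task == "conversion_classification") df <- df[df$group == "MCI", ]
    if (is.null(params)) abort("`params` needed to generate volumes")
    volumes <- prepare_volumes(df, params, enhance)
  }
  runs <- list()
  rows <- list()
  for (g in groups) {
    cfg_g <- ablation_variant(model_cfg, g)
    run <- run_experiment(cohort, task, horizon, score = score,
                          model_cfg = cfg_g, train_cfg = train_cfg,
                          params = params, volumes = volumes,
                          seed = seed, verbose = verbose)
    runs[[g]] <- run
    rows[[g]] <- dplyr::bind_cols(tibble::tibble(group = g), run$pooled,
                                  tibble::tibble(split_hash = run$split_hash))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "runs") <- runs
  class(out) <- c("mfsedrn_ablation", class(out))
  out
}

#' @export
print.mfsedrn_run <- function(x, ...) {
  cat(sprintf("<mfsedrn_run: %s @ %s%s, n = %d>\n", x$task, x$horizon,
              if (!is.na(x$score)) paste0(" (", x$score, ")") else "", x$n))
  print(x$pooled)
  invisible(x)
}

#' Tidy a cross-validated run
#'
#' @param x An `mfsedrn_run`.
#' @param ... Unused.
#' @return Per-fold validation metrics as a tibble.
#' @export
tidy.mfsedrn_run <- function(x, ...) x$metrics

#' One-row summary of a cross-validated run
#'
#' @param x An `mfsedrn_run`.
#' @param ... Unused.
#' @return A one-row tibble of pooled validation metrics, with task,
#'   horizon and cohort size.
#' @export
glance.mfsedrn_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(task = x$task, horizon = x$horizon, score = x$score),
    x$pooled
  )
}

#' @export
tidy.mfsedrn_ablation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot a cross-validated run
#'
#' Classification runs show the pooled ROC curve (with the chance
#' diagonal); regression runs show observed versus predicted scores per
#' fold.
#'
#' @param object An `mfsedrn_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfsedrn_run <- function(object, ...) {
  if (object$task == "conversion_classification") {
    lab <- as_binary_labels(object$predictions$observed)
    ra <- roc_auc(lab, object$predictions$predicted)
    ggplot2::ggplot(ra$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
      ggplot2::coord_equal() +
      ggplot2::labs(
        title = sprintf("Conversion prediction at %s", object$horizon),
        subtitle = sprintf("pooled AUC = %.3f over %d MCI subjects",
                           ra$auc, object$n),
        x = "false positive rate", y = "true positive rate"
      ) +
      ggplot2::theme_minimal()
  } else {
    dd <- object$predictions
    dd$observed <- as.numeric(dd$observed)
    ggplot2::ggplot(dd, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                     colour = factor(.data$fold))) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(
        title = sprintf("%s prediction at %s", object$score, object$horizon),
        subtitle = sprintf("pooled RMSE = %.2f, MAE = %.2f",
                           object$pooled$rmse, object$pooled$mae),
        x = "observed score", y = "predicted score", colour = "fold"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot training histories of a run
#'
#' @param run An `mfsedrn_run` trained with the network (not an injected
#'   predictor).
#' @return A ggplot of per-epoch training loss per fold.
#' @export
plot_history <- function(run) {
  if (!length(run$histories)) abort("run has no training histories")
  hh <- dplyr::bind_rows(lapply(seq_along(run$histories), function(i) {
    dplyr::mutate(run$histories[[i]], fold = i)
  }))
  ggplot2::ggplot(hh, ggplot2::aes(x = .data$epoch, y = .data$train_loss,
                                   colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss", colour = "fold") +
    ggplot2::theme_minimal()
}
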