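#' Training configuration
#'
#' Defaults follow the reference training recipe: score regression trains for 150 rounds
#' with batch size 8, learning rate 1e-4 and mean-square-error loss;
#' conversion classification trains for 100 rounds with batch size 4,
#' learning rate 1e-4 and cross-entropy loss. The optimizer is Adam in both
#' tasks, with L1 and L2 penalties on the convolution and fully connected
#' weight matrices (coefficients configurable; defaults 1e-5 and 1e-4).
#'
#' @param task `"score_regression"` or `"conversion_classification"`.
#' @param epochs,batch_size,lr Override the task defaults.
#' @param l1_coeff,l2_coeff Regularization coefficients (penalty
#'   `l1*||w||_1 + l2*||w||_2^2` on weight matrices, not on biases or
#'   normalization parameters).
#' @param folds Number of cross-validation folds (default 5).
#' @param repeats Number of repeated random-sampling rounds of the k-fold
#'   split.
#' @param seed Seed controlling initialization and batch order.
#' @return A `train_config` object.
#' @export
train_config <- function(task = c("score_regression",
                                  "conversion_classification"),
                         epochs = NULL, batch_size = NULL, lr = 1e-4,
                         l1_coeff = 1e-5, l2_coeff = 1e-4,
                         folds = 5L, repeats = 1L, seed = 1L) {
  task <- match.arg(task)
  defaults <- if (task == "score_regression") {
    list(epochs = 150L, batch_size = 8L, loss = "mse")
  } else {
    list(epochs = 100L, batch_size = 4L, loss = "cross_entropy")
  }
  structure(list(
    task = task,
    epochs = check_positive_int(epochs %||% defaults$epochs, "epochs"),
    batch_size = check_positive_int(batch_size %||% defaults$batch_size,
                                    "batch_size"),
    lr = lr,
    loss = defaults$loss,
    l1_coeff = l1_coeff,
    l2_coeff = l2_coeff,
    folds = check_positive_int(folds, "folds", min = 2L),
    repeats = check_positive_int(repeats, "repeats"),
    seed = seed
  ), class = "train_config")
}

loss_grad <- function(out, y, loss) {
  n <- nrow(out)
  if (loss == "mse") {
    r <- out[, 1] - y
    list(loss = mean(r * r), grad = matrix(2 * r / n, ncol = 1))
  } else {
    y <- as.integer(y)
    m <- apply(out, 1, max)
    e <- exp(out - m)
    p <- e / rowSums(e)
    ll <- -mean(log(pmax(p[cbind(seq_len(n), y + 1L)], 1e-12)))
    g <- p
    g[cbind(seq_len(n), y + 1L)] <- g[cbind(seq_len(n), y + 1L)] - 1
    list(loss = ll, grad = g / n)
  }
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Weight matrices (".W" entries) carry the L1/L2 penalties.
is_weight <- function(nm) endsWith(nm, ".W")

#' Train a model
#'
#' Minimizes the task loss plus `l1*||w||_1 + l2*||w||_2^2` with Adam over
#' seeded mini-batches. Batch-normalization running statistics are updated
#' during the forward passes. A non-finite loss aborts with a diagnostic
#' naming the epoch and batch.
#'
#' @param model A built [build_model()] network.
#' @param data A list with `x` (5-axis batch array or list of volumes),
#'   `tab` (tabular matrix or NULL) and `y` (targets: numeric scores, or
#'   0/1 conversion labels).
#' @param config A [train_config()] whose task matches the model's.
#' @param validation Optional list like `data` used only to record a
#'   per-epoch validation loss.
#' @param verbose Print per-epoch losses?
#' @return A list with the trained `model` and a `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train <- function(model, data, config, validation = NULL, verbose = FALSE) {
  if (!inherits(model, "mfsedrn_model")) abort("`model` must be an mfsedrn_model")
  if (!inherits(config, "train_config")) abort("`config` must be a train_config")
  if (model$config$task != config$task) {
    abort("model task and training task disagree")
  }
  x <- if (is.list(data$x) && !is.array(data$x)) stack_volumes(data$x) else data$x
  y <- data$y
  n <- dim(x)[1]
  if (config$loss == "cross_entropy") y <- as_binary_labels(y)
  state <- adam_init(model$params)
  history <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep_loss <- 0
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        xb <- x[idx, , , , , drop = FALSE]
        tb <- if (is.null(data$tab)) NULL else data$tab[idx, , drop = FALSE]
        fwd <- model_forward(model, xb, tb, training = TRUE)
        model$buffers <- fwd$buffers
        lg <- loss_grad(fwd$out, y[idx], config$loss)
        if (!is.finite(lg$loss)) {
          abort(sprintf("non-finite loss at epoch %d, batch %d", ep, bi))
        }
        grads <- model_backward(model, fwd, lg$grad)
        if (config$l1_coeff > 0 || config$l2_coeff > 0) {
          for (nm in names(grads)) {
            if (is_weight(nm) && !is.null(grads[[nm]])) {
              grads[[nm]] <- grads[[nm]] +
                config$l1_coeff * sign(model$params[[nm]]) +
                2 * config$l2_coeff * model$params[[nm]]
            }
          }
        }
        upd <- adam_step(model$params, grads, state, config$lr)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      val_loss <- NA_real_
      if (!is.null(validation)) {
        val_loss <- evaluate_loss(model, validation, config)
      }
      history[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / n,
                                      val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %s", ep, ep_loss / n,
                        ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
      }
    }
  })
  list(model = model, history = dplyr::bind_rows(history))
}

evaluate_loss <- function(model, data, config) {
  x <- if (is.list(data$x) && !is.array(data$x)) stack_volumes(data$x) else data$x
  y <- data$y
  if (config$loss == "cross_entropy") y <- as_binary_labels(y)
  fwd <- model_forward(model, x, data$tab, training = FALSE)
  loss_grad(fwd$out, y, config$loss)$loss
}

#' Repeated (stratified) k-fold splits
#'
#' Each repeat freshly shuffles the ids (seeded) and deals them into
#' near-equal folds; when labels are supplied the split is stratified so
#' every fold receives a proportional share of each class. Folds partition
#' the ids within a repeat.
#'
#' @param ids Subject identifiers (length >= `folds`).
#' @param labels Optional class labels for stratification.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeated rounds.
#' @param seed Seed for the shuffles.
#' @return A tibble with columns `repeat_idx`, `fold`, and list-columns
#'   `train` and `val` of id vectors.
#' @export
make_folds <- function(ids, labels = NULL, folds = 5L, repeats = 1L,
                       seed = 1L) {
  folds <- check_positive_int(folds, "folds", min = 2L)
  repeats <- check_positive_int(repeats, "repeats")
  n <- length(ids)
  if (n < folds) abort(sprintf("need at least %d ids for %d folds", folds, folds))
  if (!is.null(labels) && length(labels) != n) abort("labels/ids length mismatch")
  out <- list()
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      assign_fold <- integer(n)
      if (is.null(labels)) {
        assign_fold[sample.int(n)] <- rep_len(seq_len(folds), n)
      } else {
        for (lv in unique(labels)) {
          pos <- which(labels == lv)
          assign_fold[pos[sample.int(length(pos))]] <-
            rep_len(seq_len(folds), length(pos))
        }
      }
      for (f in seq_len(folds)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          repeat_idx = r, fold = f,
          train = list(ids[assign_fold != f]),
          val = list(ids[assign_fold == f])
        )
      }
    }
  })
  dplyr::bind_rows(out)
}
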