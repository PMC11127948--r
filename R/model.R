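#' Network configuration
#'
#' Describes the full architecture: a 7x7x7 stem convolution (stride 2)
#' followed by a 3x3x3 hybrid (multifusion) pooling layer, four stages of
#' squeeze-and-excitation dilated residual blocks (16 blocks in the default
#' 3/4/6/3 plan with widths 64/128/256/512; stage transitions downsample via
#' stride-2 projection shortcuts), a global hybrid pooling layer, fusion of
#' the image feature vector with the tabular features, and a fully connected
#' task head (one output for score regression, two logits for conversion
#' classification).
#'
#' @param task `"score_regression"` or `"conversion_classification"`.
#' @param in_channels Image channels (structural MRI volumes have 1).
#' @param stage_widths Four channel widths, one per stage.
#' @param blocks_per_stage Four nonnegative block counts (default sums
#'   to 16).
#' @param dilation Dilation rate of each block's first convolution.
#' @param se_reduction Squeeze-and-excitation bottleneck ratio; must divide
#'   every stage width.
#' @param fusion_dim Width of the fused feature layer.
#' @param tabular_dim Number of tabular features (the 8 default features:
#'   MMSE, ADAS-11, CDRSB, RAVLT immediate, ApoE4 allele count,
#'   A-beta 42/40 ratio, t-tau, p-tau).
#' @param no_dc,no_se,no_mf_pool,no_fusion Ablation flags: revert dilations
#'   to 1, drop the squeeze-and-excitation stages, replace hybrid pooling by
#'   max pooling only, or drop the tabular branch.
#' @return A `model_config` object.
#' @export
model_config <- function(task = c("score_regression",
                                  "conversion_classification"),
                         in_channels = 1L,
                         stage_widths = c(64L, 128L, 256L, 512L),
                         blocks_per_stage = c(3L, 4L, 6L, 3L),
                         dilation = 2L,
                         se_reduction = 16L,
                         fusion_dim = 64L,
                         tabular_dim = 8L,
                         no_dc = FALSE, no_se = FALSE,
                         no_mf_pool = FALSE, no_fusion = FALSE) {
  task <- match.arg(task)
  stage_widths <- check_positive_int(stage_widths, "stage_widths")
  blocks_per_stage <- check_positive_int(blocks_per_stage,
                                         "blocks_per_stage", min = 0L)
  if (length(stage_widths) != 4L || length(blocks_per_stage) != 4L) {
    abort("`stage_widths` and `blocks_per_stage` must have length 4")
  }
  se_reduction <- check_positive_int(se_reduction, "se_reduction")
  used <- stage_widths[blocks_per_stage > 0L]
  if (!no_se && length(used) && any(used %% se_reduction != 0L)) {
    abort("`se_reduction` must divide every used stage width")
  }
  structure(list(
    task = task,
    in_channels = check_positive_int(in_channels, "in_channels"),
    stem_kernel = 7L, stem_stride = 2L,
    stage_widths = stage_widths,
    blocks_per_stage = blocks_per_stage,
    dilation = check_positive_int(dilation, "dilation"),
    se_reduction = se_reduction,
    fusion_dim = check_positive_int(fusion_dim, "fusion_dim"),
    tabular_dim = check_positive_int(tabular_dim, "tabular_dim"),
    no_dc = isTRUE(no_dc), no_se = isTRUE(no_se),
    no_mf_pool = isTRUE(no_mf_pool), no_fusion = isTRUE(no_fusion)
  ), class = "model_config")
}

#' The five ablation groups plus the full model
#'
#' Row labels of the ablation report, in report order.
#' @return Character vector of the six group names.
#' @export
ablation_groups <- function() {
  c("Without DC, SE and MF-pool", "Without SE", "Without MF-pool",
    "Without DC", "Without multi-feature fusion", "MFSE-DRN")
}

#' Derive an ablation variant of a configuration
#'
#' @param config A [model_config()].
#' @param group One of [ablation_groups()]: the triple ablation composes the
#'   dilation, squeeze-and-excitation and hybrid-pooling removals;
#'   `"MFSE-DRN"` returns the configuration unchanged (full model).
#' @return The modified `model_config`.
#' @export
ablation_variant <- function(config, group) {
  if (!inherits(config, "model_config")) abort("`config` must be a model_config")
  groups <- ablation_groups()
  if (!is.character(group) || length(group) != 1L || !group %in% groups) {
    abort(sprintf("unknown ablation group '%s'; expected one of: %s",
                  as.character(group)[1], paste(groups, collapse = "; ")))
  }
  flags <- switch(group,
    "Without DC, SE and MF-pool" = c("no_dc", "no_se", "no_mf_pool"),
    "Without SE" = "no_se",
    "Without MF-pool" = "no_mf_pool",
    "Without DC" = "no_dc",
    "Without multi-feature fusion" = "no_fusion",
    "MFSE-DRN" = character(0)
  )
  for (f in flags) config[[f]] <- TRUE
  config
}

#' Build the network
#'
#' Assembles the trunk (stem convolution, hybrid pooling, the four block
#' stages, global hybrid pooling), the fusion layer and the task head, and
#' randomly initializes all weights (He-style, seeded).
#'
#' @param config A [model_config()].
#' @param seed Seed for weight initialization.
#' @return An object of class `mfsedrn_model` holding the layer plan, a flat
#'   named parameter list and the batch-normalization buffers.
#' @export
build_model <- function(config, seed = 1L) {
  if (!inherits(config, "model_config")) abort("`config` must be a model_config")
  pool_variant <- if (config$no_mf_pool) "max" else "mf"
  dil <- if (config$no_dc) 1L else config$dilation
  nodes <- list(
    list(name = "stem", type = "conv", k = rep(config$stem_kernel, 3L),
         stride = config$stem_stride, pad = (config$stem_kernel - 1L) %/% 2L,
         dil = 1L, cin = config$in_channels, cout = config$stage_widths[1]),
    list(name = "stem_bn", type = "bn", channels = config$stage_widths[1]),
    list(name = "stem_relu", type = "relu"),
    list(name = "stem_pool", type = "pool", window = c(3L, 3L, 3L),
         stride = 2L, pad = 1L, variant = pool_variant)
  )
  cin <- config$stage_widths[1]
  for (s in seq_len(4L)) {
    for (b in seq_len(config$blocks_per_stage[s])) {
      cout <- config$stage_widths[s]
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blk <- sedrb_config(cin, cout, stride = stride, dilation = dil,
                          use_se = !config$no_se,
                          se_reduction = config$se_reduction)
      nodes[[length(nodes) + 1L]] <- list(
        name = sprintf("s%db%d", s, b), type = "sedrb", config = blk
      )
      cin <- cout
    }
  }
  nodes[[length(nodes) + 1L]] <- list(name = "gpool", type = "gpool",
                                      variant = pool_variant)
  model <- structure(list(config = config, nodes = nodes), class = "mfsedrn_model")
  img_dim <- cin
  fusion_in <- img_dim + if (config$no_fusion) 0L else config$tabular_dim
  out_dim <- if (config$task == "score_regression") 1L else 2L

  params <- list()
  buffers <- list()
  with_seed(seed, {
    for (nd in nodes) {
      if (nd$type == "conv") {
        w <- init_conv(nd$cout, nd$cin, nd$k)
        params[[paste0(nd$name, ".W")]] <- w$W
        params[[paste0(nd$name, ".b")]] <- w$b
      } else if (nd$type == "bn") {
        w <- init_bn(nd$channels)
        params[[paste0(nd$name, ".gamma")]] <- w$gamma
        params[[paste0(nd$name, ".beta")]] <- w$beta
        buffers[[paste0(nd$name, ".rm")]] <- w$rm
        buffers[[paste0(nd$name, ".rv")]] <- w$rv
      } else if (nd$type == "sedrb") {
        wts <- sedrb_init_raw(nd$config)
        for (part in names(wts)) {
          for (nm in names(wts[[part]])) {
            key <- paste0(nd$name, ".", part, ".", nm)
            if (nm %in% c("rm", "rv")) {
              buffers[[key]] <- wts[[part]][[nm]]
            } else {
              params[[key]] <- wts[[part]][[nm]]
            }
          }
        }
      }
    }
    fw <- init_linear(fusion_in, config$fusion_dim)
    params[["fusion.W"]] <- fw$W
    params[["fusion.b"]] <- fw$b
    hw <- init_linear(config$fusion_dim, out_dim,
                      sd = sqrt(1 / config$fusion_dim))
    params[["head.W"]] <- hw$W
    params[["head.b"]] <- hw$b
  })
  model$params <- params
  model$buffers <- buffers
  model$img_dim <- img_dim
  model$out_dim <- out_dim
  model
}

# Gather the nested weight view a block forward expects from the flat
# parameter and buffer lists.
block_weights <- function(model, name) {
  pick <- function(lst, key) {
    pre <- paste0(name, ".")
    hit <- names(lst)[startsWith(names(lst), pre)]
    out <- list()
    for (h in hit) {
      rest <- strsplit(sub(pre, "", h, fixed = TRUE), ".", fixed = TRUE)[[1]]
      out[[rest[1]]][[rest[2]]] <- lst[[h]]
    }
    out
  }
  w <- pick(model$params, name)
  b <- pick(model$buffers, name)
  for (part in names(b)) w[[part]] <- c(w[[part]], b[[part]])
  w
}

model_forward <- function(model, x, tab = NULL, training = FALSE) {
  cfg <- model$config
  p <- model$params
  buf <- model$buffers
  caches <- vector("list", length(model$nodes))
  names(caches) <- vapply(model$nodes, `[[`, "", "name")
  h <- x
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    if (nd$type == "conv") {
      o <- conv3d_fw(h, p[[paste0(nd$name, ".W")]], p[[paste0(nd$name, ".b")]],
                     stride = nd$stride, pad = nd$pad, dil = nd$dil)
    } else if (nd$type == "bn") {
      o <- bn_fw(h, p[[paste0(nd$name, ".gamma")]],
                 p[[paste0(nd$name, ".beta")]],
                 buf[[paste0(nd$name, ".rm")]], buf[[paste0(nd$name, ".rv")]],
                 training)
      buf[[paste0(nd$name, ".rm")]] <- o$rm
      buf[[paste0(nd$name, ".rv")]] <- o$rv
    } else if (nd$type == "relu") {
      o <- relu_fw(h)
    } else if (nd$type == "pool") {
      o <- pool_layer_fw(h, nd$window, nd$stride, nd$pad, nd$variant)
    } else if (nd$type == "gpool") {
      o <- gpool_fw(h, nd$variant)
    } else if (nd$type == "sedrb") {
      wts <- block_weights(model, nd$name)
      o <- sedrb_fw(h, nd$config, wts, training)
      for (bn in names(o$buffers)) {
        buf[[paste0(nd$name, ".", bn, ".rm")]] <- o$buffers[[bn]]$rm
        buf[[paste0(nd$name, ".", bn, ".rv")]] <- o$buffers[[bn]]$rv
      }
    }
    h <- o$y
    caches[[i]] <- o$cache
  }
  img_vec <- h # n x img_dim
  fz <- fuse_forward(img_vec, tab, p, cfg)
  out <- sweep(fz$f %*% p[["head.W"]], 2, p[["head.b"]], "+")
  list(out = out, img_vec = img_vec, caches = caches, fuse = fz$cache,
       buffers = buf)
}

fuse_forward <- function(img_vec, tab, p, cfg) {
  if (cfg$no_fusion) {
    z <- img_vec
  } else {
    if (is.null(tab)) abort("model was built with tabular fusion: `tab` is required")
    tab <- as.matrix(tab)
    if (ncol(tab) != cfg$tabular_dim) {
      abort(sprintf("expected %d tabular features, got %d",
                    cfg$tabular_dim, ncol(tab)))
    }
    if (nrow(tab) != nrow(img_vec)) {
      abort("image batch and tabular batch sizes differ")
    }
    z <- cbind(img_vec, tab)
  }
  lin <- linear_fw(z, p[["fusion.W"]], p[["fusion.b"]])
  act <- elu_fw(lin$y)
  list(f = act$y, cache = list(lin = lin$cache, act = act$cache,
                               ncol_img = ncol(img_vec)))
}

model_backward <- function(model, fwd, gout) {
  p <- model$params
  grads <- list()
  gf <- tcrossprod(gout, p[["head.W"]])
  grads[["head.W"]] <- crossprod(fwd$fuse$act$y, gout)
  grads[["head.b"]] <- colSums(gout)
  gz <- elu_bw(fwd$fuse$act, gf)
  lb <- linear_bw(fwd$fuse$lin, p[["fusion.W"]], gz)
  grads[["fusion.W"]] <- lb$gW
  grads[["fusion.b"]] <- lb$gb
  gimg <- lb$gx[, seq_len(fwd$fuse$ncol_img), drop = FALSE]
  g <- gimg
  for (i in rev(seq_along(model$nodes))) {
    nd <- model$nodes[[i]]
    cc <- fwd$caches[[i]]
    if (nd$type == "conv") {
      o <- conv3d_bw(cc, p[[paste0(nd$name, ".W")]], g, need_gx = i > 1L)
      grads[[paste0(nd$name, ".W")]] <- o$gW
      grads[[paste0(nd$name, ".b")]] <- o$gb
      g <- o$gx
    } else if (nd$type == "bn") {
      o <- bn_bw(cc, p[[paste0(nd$name, ".gamma")]], g)
      grads[[paste0(nd$name, ".gamma")]] <- o$ggamma
      grads[[paste0(nd$name, ".beta")]] <- o$gbeta
      g <- o$gx
    } else if (nd$type == "relu") {
      g <- relu_bw(cc, g)
    } else if (nd$type == "pool") {
      g <- pool_layer_bw(cc, g)
    } else if (nd$type == "gpool") {
      g <- gpool_bw(cc, g)
    } else if (nd$type == "sedrb") {
      wts <- block_weights(model, nd$name)
      o <- sedrb_bw(cc, wts, g)
      for (part in names(o$grads)) {
        for (nm in names(o$grads[[part]])) {
          grads[[paste0(nd$name, ".", part, ".", nm)]] <- o$grads[[part]][[nm]]
        }
      }
      g <- o$gx
    }
  }
  grads
}

#' Fuse image and tabular feature vectors
#'
#' Concatenates the image feature vector (from the global hybrid pooling
#' layer) with the tabular feature vector and passes the result through a
#' fully connected layer with an exponential-linear-unit activation. Under
#' the `no_fusion` ablation the tabular branch is dropped and the layer acts
#' on the image features alone.
#'
#' @param image_vec `n x p` matrix of image features.
#' @param tabular `n x tabular_dim` matrix (or NULL under `no_fusion`).
#' @param weights List with `W` (`(p + tabular_dim) x fusion_dim`) and `b`.
#' @param no_fusion Drop the tabular branch?
#' @return The fused `n x fusion_dim` feature matrix.
#' @export
fuse_features <- function(image_vec, tabular, weights, no_fusion = FALSE) {
  image_vec <- as.matrix(image_vec)
  z <- if (no_fusion) {
    image_vec
  } else {
    tabular <- as.matrix(tabular)
    if (nrow(tabular) != nrow(image_vec)) {
      abort("image and tabular batches differ in size")
    }
    cbind(image_vec, tabular)
  }
  if (nrow(weights$W) != ncol(z)) {
    abort(sprintf("fusion weights expect %d inputs, got %d",
                  nrow(weights$W), ncol(z)))
  }
  elu_fw(linear_fw(z, weights$W, weights$b)$y)$y
}

#' Count model parameters
#' @param model An `mfsedrn_model`.
#' @return Total number of trainable parameters.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Layer census
#'
#' Counts layers from the construction-time registry. The headline
#' accounting counts the stem convolution, the convolutions inside residual
#' blocks (two per block), the hybrid pooling layers and the multifeature
#' fusion layer; batch normalization, activations, squeeze-and-excitation
#' bottleneck layers, projection-shortcut convolutions and the head are
#' reported separately in `aux` and excluded from `total`. The default
#' configuration yields 36 layers: 32 block convolutions (16 blocks), one
#' 7x7x7 stem convolution, 2 hybrid pooling layers and one fusion layer.
#'
#' @param model An `mfsedrn_model` (or a [model_config()], which is built
#'   with zero-cost introspection).
#' @return An object of class `mfsedrn_census`.
#' @export
layer_census <- function(model) {
  if (inherits(model, "model_config")) {
    cfg <- model
  } else if (inherits(model, "mfsedrn_model")) {
    cfg <- model$config
  } else {
    abort("`model` must be an mfsedrn_model or model_config")
  }
  nblocks <- sum(cfg$blocks_per_stage)
  nproj <- 0L
  cin <- cfg$stage_widths[1]
  for (s in seq_len(4L)) {
    for (b in seq_len(cfg$blocks_per_stage[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      if (cin != cfg$stage_widths[s] || stride != 1L) nproj <- nproj + 1L
      cin <- cfg$stage_widths[s]
    }
  }
  census <- list(
    stem_conv = 1L,
    conv_in_blocks = 2L * nblocks,
    se_drb = nblocks,
    mf_pool = if (cfg$no_mf_pool) 0L else 2L,
    fusion = if (cfg$no_fusion) 0L else 1L,
    aux = list(
      bn = 1L + 2L * nblocks,
      se_stages = if (cfg$no_se) 0L else nblocks,
      se_fc = if (cfg$no_se) 0L else 2L * nblocks,
      shortcut_conv = nproj,
      max_pool_only = if (cfg$no_mf_pool) 2L else 0L,
      head_fc = 1L
    )
  )
  census$total <- census$stem_conv + census$conv_in_blocks +
    census$mf_pool + census$fusion
  structure(census, class = "mfsedrn_census")
}

#' @export
print.mfsedrn_census <- function(x, ...) {
  cat("Layer census\n")
  cat(sprintf("  stem conv:        %d\n", x$stem_conv))
  cat(sprintf("  block convs:      %d (%d SE-DRBs)\n",
              x$conv_in_blocks, x$se_drb))
  cat(sprintf("  MF-Pool layers:   %d\n", x$mf_pool))
  cat(sprintf("  fusion layers:    %d\n", x$fusion))
  cat(sprintf("  total:            %d\n", x$total))
  cat(sprintf("  (aux, excluded: %s)\n",
              paste(sprintf("%s=%d", names(x$aux), unlist(x$aux)),
                    collapse = ", ")))
  invisible(x)
}

#' Export a layer census as JSON
#' @param census An `mfsedrn_census` (or a model, which is censused first).
#' @return A JSON string.
#' @export
census_json <- function(census) {
  if (!inherits(census, "mfsedrn_census")) census <- layer_census(census)
  jsonlite::toJSON(unclass(census), auto_unbox = TRUE, pretty = TRUE)
}

#' Predict from a built model
#'
#' Runs the network in evaluation mode. For score regression returns the
#' predicted score per sample; for conversion classification returns the
#' progressive-MCI probability (softmax of the two logits).
#'
#' @param object An `mfsedrn_model`.
#' @param volumes A 5-axis batch array `(n, c, d, h, w)` or a list of
#'   single-subject volumes (stacked with [stack_volumes()]).
#' @param tabular Tabular feature matrix (NULL under `no_fusion`).
#' @param type `"response"` (default) or `"logits"`.
#' @param ... Unused.
#' @return A numeric vector (or logit matrix).
#' @export
predict.mfsedrn_model <- function(object, volumes, tabular = NULL,
                                  type = c("response", "logits"), ...) {
  type <- match.arg(type)
  if (is.list(volumes) && !is.array(volumes)) volumes <- stack_volumes(volumes)
  fwd <- model_forward(object, volumes, tabular, training = FALSE)
  if (type == "logits") return(fwd$out)
  if (object$config$task == "score_regression") {
    as.numeric(fwd$out[, 1])
  } else {
    e <- exp(fwd$out - apply(fwd$out, 1, max))
    as.numeric(e[, 2] / rowSums(e))
  }
}

#' Stack single-subject volumes into a batch
#'
#' @param vols List of 3-axis `(d, h, w)` or 4-axis `(c, d, h, w)` arrays of
#'   identical shape.
#' @return A 5-axis `(n, c, d, h, w)` array.
#' @export
stack_volumes <- function(vols) {
  if (!length(vols)) abort("empty volume list")
  v1 <- as_volume(vols[[1]])
  out <- array(0, dim = c(length(vols), dim(v1)[-1]))
  for (i in seq_along(vols)) out[i, , , , ] <- as_volume(vols[[i]])
  out
}

#' @export
print.mfsedrn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mfsedrn_model: %s>\n", cfg$task))
  cat(sprintf("  stages %s x widths %s, dilation %d%s\n",
              paste(cfg$blocks_per_stage, collapse = "/"),
              paste(cfg$stage_widths, collapse = "/"),
              if (cfg$no_dc) 1L else cfg$dilation,
              if (cfg$no_se) ", no SE" else ""))
  flags <- c("no_dc", "no_se", "no_mf_pool", "no_fusion")
  on <- flags[vapply(flags, function(f) isTRUE(cfg[[f]]), logical(1))]
  if (length(on)) cat(sprintf("  ablations: %s\n", paste(on, collapse = ", ")))
  cat(sprintf("  parameters: %s\n", format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Write / read a model configuration as YAML
#' @param config A [model_config()].
#' @param path File path.
#' @return `read_model_config` returns a `model_config`.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(model_config, raw[setdiff(names(raw), c("stem_kernel", "stem_stride"))])
}

#' Save / load model weights
#'
#' Serializes parameters, buffers and configuration to a single checkpoint
#' file (RDS).
#' @param model An `mfsedrn_model`.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               buffers = model$buffers), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(do.call(model_config,
                               ck$config[setdiff(names(ck$config),
                                                 c("stem_kernel", "stem_stride"))]))
  model$params <- ck$params
  model$buffers <- ck$buffers
  model
}
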