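# Dual-decoder mask / incoherent-region heads. The mask decoder consumes
# 14x14 ROI features and predicts a 28x28 instance mask; the incoherent
# decoder consumes 28x28 ROI features and predicts the instance's
# incoherent-region mask at 28 or 56. Two pixel affinity learning modules
# (PALM) couple the branches: a shared squeeze-and-excitation representation
# built from branch-softmax-reweighted features is added back to both. The
# backbone/RPN scaffold of a full detector is out of scope; a pluggable
# feature provider (here a tiny trainable encoder over proposal crops)
# supplies the ROI features.

#' Configuration of the dual-decoder heads
#'
#' @param mask_roi,inc_roi ROI feature sizes of the two branches (14 / 28).
#' @param mask_out Mask-decoder output size; must equal `2 * mask_roi`.
#' @param inc_out Incoherent-decoder output size, 28 or 56.
#' @param use_palm Enable the pixel affinity learning modules.
#' @param supervision `"incoherent"` or `"boundary"` (the Laplacian
#'   boundary-supervision baseline).
#' @param lambda_inc Weight of the local-incoherent loss term (default 2).
#' @param channels Feature channel width `c`.
#' @param n_refine Cascaded 3x3 refinement convolutions per stream.
#' @return A `head_config` list.
#' @export
head_config <- function(mask_roi = 14L, inc_roi = 28L, mask_out = 28L,
                        inc_out = 56L, use_palm = TRUE,
                        supervision = c("incoherent", "boundary"),
                        lambda_inc = 2, channels = 16L, n_refine = 2L) {
  supervision <- match.arg(supervision)
  if (!inc_out %in% c(28L, 56L)) abort("inc_out must be 28 or 56")
  if (mask_out != 2L * mask_roi) abort("mask_out must equal 2 * mask_roi")
  structure(
    list(mask_roi = mask_roi, inc_roi = inc_roi, mask_out = mask_out,
         inc_out = inc_out, use_palm = use_palm, supervision = supervision,
         lambda_inc = lambda_inc, channels = as.integer(channels),
         n_refine = as.integer(n_refine)),
    class = "head_config"
  )
}

palm_init <- function(c) {
  list(
    phi1 = init_conv_param(3, 2 * c, c),
    phi2 = init_conv_param(3, c, 2 * c),
    fuse = init_conv_param(3, 2 * c, c),
    se1 = init_dense_param(c, max(1L, c %/% 4L)),
    se2 = init_dense_param(max(1L, c %/% 4L), c)
  )
}

heads_init <- function(cfg) {
  c <- cfg$channels
  list(
    refine_m = lapply(seq_len(cfg$n_refine), function(i) init_conv_param(3, c, c)),
    refine_i = lapply(seq_len(cfg$n_refine), function(i) init_conv_param(3, c, c)),
    up_m = init_conv_param(2, c, c),
    palm1 = if (cfg$use_palm) palm_init(c),
    down_m = init_conv_param(3, c, c),
    down_i = init_conv_param(3, c, c),
    palm2 = if (cfg$use_palm) palm_init(c),
    out_m_up = init_conv_param(2, c, c),
    out_m = init_conv_param(1, c, 1),
    out_i_up1 = init_conv_param(2, c, c),
    out_i_up2 = if (cfg$inc_out == 56L) init_conv_param(2, c, c),
    out_i = init_conv_param(1, c, 1)
  )
}

palm_node <- function(f_m, f_i, pp) {
  f <- op_concat_c(f_m, f_i)
  f <- op_relu(op_conv(f, pp$phi1$W, pp$phi1$b))
  f <- op_conv(f, pp$phi2$W, pp$phi2$b)
  c <- dim(f_m$value)[3]
  f1 <- op_slice_c(f, seq_len(c))
  f2 <- op_slice_c(f, c + seq_len(c))
  # two-way softmax across branches: w1 + w2 = 1 at every position/channel
  w1 <- op_sigmoid(op_sub(f1, f2))
  w2 <- op_sigmoid(op_sub(f2, f1))
  fm_w <- op_mul(f_m, w1)
  fi_w <- op_mul(f_i, w2)
  fs <- op_relu(op_conv(op_concat_c(fm_w, fi_w), pp$fuse$W, pp$fuse$b))
  s <- op_sigmoid(op_dense(op_relu(op_dense(op_gap(fs), pp$se1$W, pp$se1$b)),
                           pp$se2$W, pp$se2$b))
  se_out <- op_scale_c(fs, s)
  list(f_m = op_add(se_out, f_m), f_i = op_add(se_out, f_i),
       w1 = w1, w2 = w2)
}

#' Pixel affinity learning module (forward)
#'
#' Couples the mask-branch and incoherent-branch feature grids: the
#' concatenated features pass through a compress-excite nonlinear mapping,
#' a per-position, per-channel two-way softmax reweights each branch, the
#' reweighted features fuse into a shared representation which, after
#' squeeze-and-excitation channel attention, is added back to both inputs.
#' Output shapes equal input shapes.
#'
#' @param f_m,f_i Feature arrays `h x w x c` from the two branches (equal
#'   shapes).
#' @param params PALM parameters, or `NULL` to initialize randomly.
#' @param seed Seed used when `params` is `NULL`.
#' @return A list with `f_m`, `f_i` (arrays, input shapes) and the softmax
#'   weight arrays `w1`, `w2`.
#' @export
palm_forward <- function(f_m, f_i, params = NULL, seed = 1L) {
  if (!identical(dim(f_m), dim(f_i))) abort("branch feature shapes must match")
  if (is.null(params)) {
    params <- with_preserved_rng(seed, palm_init(dim(f_m)[3]))
  }
  old <- .tape$enabled; .tape$enabled <- FALSE
  on.exit({ .tape$enabled <- old; tape_reset() })
  out <- palm_node(ag_const(f_m), ag_const(f_i), params)
  list(f_m = out$f_m$value, f_i = out$f_i$value,
       w1 = out$w1$value, w2 = out$w2$value)
}

decoders_node <- function(f_m, f_i, cfg, hp) {
  for (rp in hp$refine_m) f_m <- op_relu(op_conv(f_m, rp$W, rp$b))
  for (rp in hp$refine_i) f_i <- op_relu(op_conv(f_i, rp$W, rp$b))
  # upsample mask stream to the incoherent ROI resolution
  f_m <- op_relu(op_convt2(f_m, hp$up_m$W, hp$up_m$b))
  if (cfg$use_palm) {
    p1 <- palm_node(f_m, f_i, hp$palm1)
    f_m <- p1$f_m; f_i <- p1$f_i
  }
  # stride-2 downsample both, second PALM at the coarse scale
  f_m <- op_relu(op_conv(f_m, hp$down_m$W, hp$down_m$b, stride = 2L))
  f_i <- op_relu(op_conv(f_i, hp$down_i$W, hp$down_i$b, stride = 2L))
  if (cfg$use_palm) {
    p2 <- palm_node(f_m, f_i, hp$palm2)
    f_m <- p2$f_m; f_i <- p2$f_i
  }
  # deconvolve to the output sizes and project to probabilities
  f_m <- op_relu(op_convt2(f_m, hp$out_m_up$W, hp$out_m_up$b))
  p_m <- op_sigmoid(op_conv(f_m, hp$out_m$W, hp$out_m$b, pad = 0L))
  f_i <- op_relu(op_convt2(f_i, hp$out_i_up1$W, hp$out_i_up1$b))
  if (cfg$inc_out == 56L) {
    f_i <- op_relu(op_convt2(f_i, hp$out_i_up2$W, hp$out_i_up2$b))
  }
  p_i <- op_sigmoid(op_conv(f_i, hp$out_i$W, hp$out_i$b, pad = 0L))
  list(p_m = p_m, p_i = p_i)
}

#' Forward pass of the dual decoders
#'
#' @param f_m_roi Mask-branch ROI features, `mask_roi x mask_roi x c`.
#' @param f_i_roi Incoherent-branch ROI features, `inc_roi x inc_roi x c`.
#' @param cfg A [head_config()].
#' @param params Head parameters, or `NULL` to initialize randomly.
#' @param seed Seed used when `params` is `NULL`.
#' @return A list with probability matrices `p_m`
#'   (`mask_out` sq.) and `p_i` (`inc_out` sq.), values in `[0, 1]`.
#' @export
decoders_forward <- function(f_m_roi, f_i_roi, cfg = head_config(),
                             params = NULL, seed = 1L) {
  if (dim(f_m_roi)[1] != cfg$mask_roi || dim(f_i_roi)[1] != cfg$inc_roi) {
    abort("ROI feature sizes must match the configuration")
  }
  if (dim(f_m_roi)[3] != dim(f_i_roi)[3]) abort("branch channel widths must match")
  if (is.null(params)) {
    cfg2 <- cfg; cfg2$channels <- dim(f_m_roi)[3]
    params <- with_preserved_rng(seed, heads_init(cfg2))
  }
  old <- .tape$enabled; .tape$enabled <- FALSE
  on.exit({ .tape$enabled <- old; tape_reset() })
  out <- decoders_node(ag_const(f_m_roi), ag_const(f_i_roi), cfg, params)
  list(p_m = out$p_m$value[, , 1], p_i = out$p_i$value[, , 1])
}

# ---- losses -----------------------------------------------------------------

#' Mask-decoder loss
#'
#' Mean binary cross-entropy between the mask-decoder prediction and the
#' proposal-cropped instance mask, probabilities clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param p_m Probability matrix.
#' @param mpc Target instance mask, same shape.
#' @return Scalar loss.
#' @export
mask_loss <- function(p_m, mpc) {
  mpc <- as_mask(mpc)
  if (!all(dim(p_m) == dim(mpc))) abort("shape mismatch between p_m and mpc")
  old <- .tape$enabled; .tape$enabled <- FALSE
  on.exit(.tape$enabled <- old)
  op_bce(ag_const(p_m), as.numeric(mpc))$value
}

incoherent_loss_node <- function(p_i, mpi, minc_oi, lambda_inc) {
  term1 <- sc_add(op_dice(p_i, mpi), op_bce(p_i, mpi))
  p_local <- op_mul_const(p_i, minc_oi)
  term2 <- sc_add(op_dice(p_local, minc_oi), op_bce(p_local, minc_oi))
  sc_add(term1, sc_mul(term2, lambda_inc))
}

#' Incoherent-decoder loss
#'
#' Dice-plus-BCE of the incoherent prediction against the instance
#' incoherent mask, plus `lambda_inc` times dice-plus-BCE of the prediction
#' restricted (elementwise product) to the local incoherent region against
#' that region. The dice term uses +1 smoothing in numerator and
#' denominator.
#'
#' @param p_i Probability matrix.
#' @param mpi Instance incoherent-region target.
#' @param minc_oi Local incoherent-region target; all same shape.
#' @param lambda_inc Weight of the local term (default 2, >= 0).
#' @return Scalar loss.
#' @export
incoherent_loss <- function(p_i, mpi, minc_oi, lambda_inc = 2) {
  if (lambda_inc < 0) abort("lambda_inc must be >= 0")
  mpi <- as_mask(mpi); minc_oi <- as_mask(minc_oi)
  check_same_shape(mpi, minc_oi)
  if (!all(dim(p_i) == dim(mpi))) abort("shape mismatch between p_i and targets")
  old <- .tape$enabled; .tape$enabled <- FALSE
  on.exit(.tape$enabled <- old)
  incoherent_loss_node(ag_const(p_i), as.numeric(mpi), as.numeric(minc_oi),
                       lambda_inc)$value
}

# ---- scaled training harness ------------------------------------------------

encoder_init <- function(c) {
  list(conv1 = init_conv_param(3, 3, c), conv2 = init_conv_param(3, c, c),
       down = init_conv_param(3, c, c))
}

encoder_node <- function(rgb_node, ep) {
  f <- op_relu(op_conv(rgb_node, ep$conv1$W, ep$conv1$b))
  f_i <- op_relu(op_conv(f, ep$conv2$W, ep$conv2$b))
  f_m <- op_relu(op_conv(f_i, ep$down$W, ep$down$b, stride = 2L))
  list(f_m = f_m, f_i = f_i)
}

crop_rgb <- function(rgb, box, out_h, out_w) {
  planes <- lapply(1:3, function(ch) {
    cr <- crop_box(rgb[, , ch], box)
    bilinear_resample(cr, out_h, out_w)
  })
  array(c(planes[[1]], planes[[2]], planes[[3]]), c(out_h, out_w, 3))
}

#' Train the dual-decoder heads on fixture scenes
#'
#' Scaled training harness: proposals are ground-truth boxes with random
#' jitter; a small trainable convolutional encoder turns each proposal's
#' RGB crop into the two ROI feature grids; the heads are optimized on
#' `mask_loss + incoherent_loss` with Adam under a linear warm-up followed
#' by cosine annealing.
#'
#' @param scenes A list of `fixture_scene` objects (see [make_scene()]).
#' @param cfg A [head_config()].
#' @param iters Training iterations.
#' @param batch Proposals per iteration.
#' @param lr Peak learning rate.
#' @param warmup Fraction of iterations spent in linear warm-up.
#' @param seed Seed controlling jitter, initialization, sample order.
#' @param log_path Optional JSONL file receiving the training log.
#' @return An object of class `heads_model` with the config, parameters and
#'   a log tibble (`iteration`, `loss_mask`, `loss_inc`, `loss`,
#'   `running_loss`).
#' @export
train_heads <- function(scenes, cfg = head_config(), iters = 300L, batch = 4L,
                        lr = 1e-4, warmup = 0.1, seed = 1L, log_path = NULL) {
  if (inherits(scenes, "fixture_scene")) scenes <- list(scenes)
  # build the proposal dataset: rgb crop + supervision triple per instance
  data <- list()
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    trips <- supervision_triples(
      sc, seed = derive_seed(seed, 100L + si),
      mask_out = cfg$mask_out, inc_out = cfg$inc_out,
      supervision = cfg$supervision
    )
    for (k in seq_len(nrow(trips))) {
      tr <- trips$triple[[k]]
      if (tr$empty_crop) next
      data[[length(data) + 1]] <- list(
        rgb = crop_rgb(sc$rgb, trips$proposal[[k]], cfg$inc_roi, cfg$inc_roi),
        triple = tr
      )
    }
  }
  if (length(data) == 0) abort("no usable proposals in the scenes")

  model <- with_preserved_rng(derive_seed(seed, 0L), {
    list(encoder = encoder_init(cfg$channels), heads = heads_init(cfg))
  })
  params <- c(flatten_params(model$encoder), flatten_params(model$heads))

  log <- vector("list", iters)
  with_preserved_rng(derive_seed(seed, 1L), {
    running <- NULL
    warm_iters <- max(1, round(warmup * iters))
    for (it in seq_len(iters)) {
      lr_t <- if (it <= warm_iters) {
        lr * it / warm_iters
      } else {
        lr * 0.5 * (1 + cos(pi * (it - warm_iters) / max(1, iters - warm_iters)))
      }
      idx <- sample.int(length(data), batch, replace = TRUE)
      zero_grads(params)
      lm_tot <- li_tot <- 0
      for (i in idx) {
        tape_reset()
        d <- data[[i]]
        feats <- encoder_node(ag_const(d$rgb), model$encoder)
        out <- decoders_node(feats$f_m, feats$f_i, cfg, model$heads)
        lm <- op_bce(out$p_m, as.numeric(d$triple$mpc))
        li <- incoherent_loss_node(out$p_i, as.numeric(d$triple$mpi),
                                   as.numeric(d$triple$minc_oi), cfg$lambda_inc)
        loss <- sc_add(lm, li)
        ag_backward(loss)
        lm_tot <- lm_tot + lm$value; li_tot <- li_tot + li$value
      }
      tape_reset()
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / batch
      adam_step(params, lr_t, it)
      total <- (lm_tot + li_tot) / batch
      running <- if (is.null(running)) total else 0.95 * running + 0.05 * total
      log[[it]] <- tibble::tibble(
        iteration = it, loss_mask = lm_tot / batch, loss_inc = li_tot / batch,
        loss = total, running_loss = running
      )
    }
  })
  log <- dplyr::bind_rows(log)
  if (!is.null(log_path)) {
    write_jsonl(purrr::transpose(as.list(log)), log_path)
  }
  structure(list(cfg = cfg, model = model, log = log), class = "heads_model")
}

#' @export
print.heads_model <- function(x, ...) {
  cat(sprintf(
    "<heads_model> %s supervision, PALM %s, out %d/%d, %d iters, final loss %.4f\n",
    x$cfg$supervision, if (x$cfg$use_palm) "on" else "off",
    x$cfg$mask_out, x$cfg$inc_out, max(x$log$iteration),
    dplyr::last(x$log$running_loss)
  ))
  invisible(x)
}

#' @rdname tidy.amodal_model
#' @export
tidy.heads_model <- function(x, ...) x$log

#' @rdname tidy.amodal_model
#' @export
glance.heads_model <- function(x, ...) {
  tibble::tibble(
    supervision = x$cfg$supervision, use_palm = x$cfg$use_palm,
    mask_out = x$cfg$mask_out, inc_out = x$cfg$inc_out,
    iterations = max(x$log$iteration),
    first_loss = x$log$loss[1], final_loss = dplyr::last(x$log$running_loss)
  )
}

#' Save or load dual-decoder head weights
#'
#' Checkpoints are plain JSON (encoder and head weights flattened with
#' dimensions) plus the head configuration.
#'
#' @param model A `heads_model`.
#' @param path Checkpoint path.
#' @return `save_heads_model` returns `path` invisibly; `load_heads_model`
#'   returns the restored model (without its training log).
#' @export
save_heads_model <- function(model, path) {
  params <- c(flatten_params(model$model$encoder),
              flatten_params(model$model$heads))
  payload <- list(
    cfg = unclass(model$cfg),
    weights = lapply(params, function(p) {
      list(dim = dim(p$value) %||% length(p$value), value = as.numeric(p$value))
    })
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' @rdname save_heads_model
#' @export
load_heads_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cfg <- do.call(head_config, payload$cfg[c(
    "mask_roi", "inc_roi", "mask_out", "inc_out", "use_palm", "supervision",
    "lambda_inc", "channels", "n_refine"
  )])
  model <- with_preserved_rng(1L, {
    list(encoder = encoder_init(cfg$channels), heads = heads_init(cfg))
  })
  params <- c(flatten_params(model$encoder), flatten_params(model$heads))
  stopifnot(length(params) == length(payload$weights))
  for (i in seq_along(params)) {
    wi <- payload$weights[[i]]
    v <- as.numeric(unlist(wi$value))
    d <- as.integer(unlist(wi$dim))
    params[[i]]$value <- if (length(d) > 1) array(v, d) else v
  }
  structure(list(cfg = cfg, model = model,
                 log = tibble::tibble(iteration = integer(), loss = numeric(),
                                      loss_mask = numeric(), loss_inc = numeric(),
                                      running_loss = numeric())),
            class = "heads_model")
}

#' Predict with trained heads on a proposal crop
#'
#' @param object A `heads_model`.
#' @param rgb_crop RGB array of the proposal crop (any size; resampled to
#'   the incoherent ROI size).
#' @param ... Unused.
#' @return A list with probability matrices `p_m` and `p_i`.
#' @export
predict.heads_model <- function(object, rgb_crop, ...) {
  cfg <- object$cfg
  box <- c(x0 = 0, y0 = 0, x1 = ncol(rgb_crop), y1 = nrow(rgb_crop))
  rgb <- crop_rgb(rgb_crop, box, cfg$inc_roi, cfg$inc_roi)
  old <- .tape$enabled; .tape$enabled <- FALSE
  on.exit({ .tape$enabled <- old; tape_reset() })
  feats <- encoder_node(ag_const(rgb), object$model$encoder)
  out <- decoders_node(feats$f_m, feats$f_i, cfg, object$model$heads)
  list(p_m = out$p_m$value[, , 1], p_i = out$p_i$value[, , 1])
}
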