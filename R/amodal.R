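# The mask-completion network: a U-Net style encoder-decoder that maps the
# channel-stacked (visible occluded mask, occluder mask) pair to the
# probability grid of the occluded instance's complete mask, trained with a
# BCE loss split between the occluder region and its complement, plus the
# cross-prediction rule that orders the members of an occluding pair.

# ---- architecture -----------------------------------------------------------

unet_init <- function(depth, base, in_ch = 2L) {
  widths <- base * 2^(seq_len(depth) - 1)
  enc <- lapply(seq_len(depth), function(l) {
    cin <- if (l == 1) in_ch else widths[l - 1]
    list(c1 = init_conv_param(3, cin, widths[l]),
         c2 = init_conv_param(3, widths[l], widths[l]))
  })
  dec <- lapply(seq_len(depth - 1), function(l) {
    # decoder stage producing width[l] features at level l
    list(up = init_conv_param(2, widths[l + 1], widths[l]),
         c1 = init_conv_param(3, 2 * widths[l], widths[l]),
         c2 = init_conv_param(3, widths[l], widths[l]))
  })
  out <- init_conv_param(1, widths[1], 1)
  list(enc = enc, dec = dec, out = out, widths = widths)
}

unet_forward <- function(net, x_node) {
  depth <- length(net$enc)
  skips <- vector("list", depth)
  h <- x_node
  for (l in seq_len(depth)) {
    e <- net$enc[[l]]
    h <- op_relu(op_conv(h, e$c1$W, e$c1$b))
    h <- op_relu(op_conv(h, e$c2$W, e$c2$b))
    skips[[l]] <- h
    if (l < depth) h <- op_maxpool2(h)
  }
  for (l in rev(seq_len(depth - 1))) {
    d <- net$dec[[l]]
    h <- op_convt2(h, d$up$W, d$up$b)
    h <- op_concat_c(skips[[l]], h)
    h <- op_relu(op_conv(h, d$c1$W, d$c1$b))
    h <- op_relu(op_conv(h, d$c2$W, d$c2$b))
  }
  op_sigmoid(op_conv(h, net$out$W, net$out$b, pad = 0L))
}

#' Create an (untrained) amodal mask-completion model
#'
#' An encoder-decoder with skip connections (U-Net); the 2-channel input
#' stacks the visible occluded-instance mask and the occluder mask, the
#' 1-channel sigmoid output is the probability grid of the complete mask at
#' the same spatial size.
#'
#' @param input_size Square input side in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param depth Number of resolution levels (default 4).
#' @param base Channel width of the first level (doubling per level).
#' @param seed Seed for weight initialization.
#' @return An object of class `amodal_model`.
#' @export
amodal_unet <- function(input_size = 320L, depth = 4L, base = 32L, seed = 1L) {
  if (input_size %% 2^(depth - 1) != 0) {
    abort("input_size must be divisible by 2^(depth - 1)")
  }
  net <- with_preserved_rng(seed, unet_init(depth, base))
  structure(
    list(
      net = net,
      cfg = list(input_size = as.integer(input_size), depth = depth,
                 base = base, seed = seed),
      log = NULL, trained = FALSE
    ),
    class = "amodal_model"
  )
}

#' @export
print.amodal_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$net), function(p) length(p$value), numeric(1)))
  cat(sprintf(
    "<amodal_model> input %dx%d, depth %d, base width %d, %s (%d parameters)\n",
    x$cfg$input_size, x$cfg$input_size, x$cfg$depth, x$cfg$base,
    if (x$trained) sprintf("trained %d iters", max(x$log$iteration)) else "untrained",
    np
  ))
  invisible(x)
}

fit_to_model <- function(m, size) {
  m <- as_mask(m)
  if (nrow(m) == size && ncol(m) == size) return(m)
  resize_mask(letterbox_square(m), size, size)
}

#' Predict the amodal mask of an occluded instance
#'
#' @param x An `amodal_model`.
#' @param m_occ Visible mask of the occluded instance.
#' @param m_occder Mask of the occluder, same shape. Both are letterboxed
#'   and resized to the model input size if needed.
#' @return A list with `p_a` (probability matrix) and `m_a` (binary mask,
#'   `p_a >= 0.5`), both at the model's input size.
#' @export
amodal_forward <- function(x, m_occ, m_occder) {
  stopifnot(inherits(x, "amodal_model"))
  size <- x$cfg$input_size
  m_occ <- fit_to_model(m_occ, size)
  m_occder <- fit_to_model(m_occder, size)
  check_same_shape(m_occ, m_occder)
  old <- .tape$enabled; .tape$enabled <- FALSE
  on.exit({ .tape$enabled <- old; tape_reset() })
  inp <- ag_const(array(c(m_occ, m_occder), c(size, size, 2)))
  p <- unet_forward(x$net, inp)$value[, , 1]
  list(p_a = p, m_a = matrix(as.integer(p >= 0.5), size, size))
}

#' @rdname amodal_forward
#' @param object,... Standard predict-method arguments.
#' @export
predict.amodal_model <- function(object, m_occ, m_occder, ...) {
  amodal_forward(object, m_occ, m_occder)
}

# ---- loss -------------------------------------------------------------------

amodal_loss_node <- function(p_node, m_intact, m_occder, lambda2) {
  occ <- as.numeric(m_occder)
  inside <- op_bce(op_mul_const(p_node, m_occder), m_intact * m_occder)
  outside <- op_bce(op_mul_const(p_node, 1 - m_occder), m_intact * (1 - m_occder))
  sc_add(inside, sc_mul(outside, lambda2))
}

#' Region-weighted amodal completion loss
#'
#' BCE restricted (by elementwise product) to the occluder region, plus
#' `lambda2` times BCE restricted to its complement. The heavier weight on
#' the complement anchors the prediction to the visible evidence while the
#' occluder-region term drives completion.
#'
#' @param p_a Probability matrix in `[0, 1]`.
#' @param m_intact Ground-truth complete mask.
#' @param m_occder Occluder mask; all same shape.
#' @param lambda2 Complement-region weight (default 5).
#' @return The scalar loss.
#' @export
amodal_loss <- function(p_a, m_intact, m_occder, lambda2 = 5) {
  if (lambda2 < 0) abort("lambda2 must be >= 0")
  m_intact <- as_mask(m_intact); m_occder <- as_mask(m_occder)
  check_same_shape(m_intact, m_occder)
  if (!all(dim(p_a) == dim(m_intact))) abort("p_a shape must match the masks")
  old <- .tape$enabled; .tape$enabled <- FALSE
  on.exit(.tape$enabled <- old)
  amodal_loss_node(ag_const(p_a), m_intact, m_occder, lambda2)$value
}

# ---- training ---------------------------------------------------------------

sample_arrays <- function(s, size) {
  list(
    x = array(c(fit_to_model(s$m_occ_s, size), fit_to_model(s$m_occder_s, size)),
              c(size, size, 2)),
    occder = matrix(as.numeric(fit_to_model(s$m_occder_s, size)), size, size),
    target = matrix(as.numeric(fit_to_model(s$m_intact_s, size)), size, size)
  )
}

#' Train the amodal mask-completion model
#'
#' Optimizes [amodal_loss()] with Adam over a stream of synthesis samples.
#' Defaults follow the production recipe (learning rate 1e-4, first-moment
#' coefficient 0.9, weight decay 5e-4); scaled-down experiments override
#' the iteration count, input size and width.
#'
#' @param samples A manifest tibble from [synthesize_dataset()], a list of
#'   `synthesis_sample` objects, or a data frame with list-columns
#'   `m_occ`/`m_occder`/`m_intact` (as from [scene_occlusion_pairs()]).
#' @param model An `amodal_model` to continue training, or `NULL` to create
#'   one from the remaining arguments.
#' @param input_size,depth,base Architecture (see [amodal_unet()]).
#' @param iters Training iterations.
#' @param batch Samples per iteration.
#' @param lr,beta1,weight_decay Adam hyperparameters.
#' @param lambda2 Loss weight of the non-occluder region.
#' @param seed Seed controlling initialization and sample order.
#' @param log_every Record the loss every this many iterations.
#' @return A trained `amodal_model`; its `log` is a tibble of `iteration`,
#'   `loss`, `running_loss`.
#' @export
train_amodal <- function(samples, model = NULL, input_size = 64L, depth = 4L,
                         base = 32L, iters = 300L, batch = 4L, lr = 1e-4,
                         beta1 = 0.9, weight_decay = 5e-4, lambda2 = 5,
                         seed = 1L, log_every = 1L) {
  items <- if (is.data.frame(samples) && "sample" %in% names(samples)) {
    samples$sample
  } else if (is.data.frame(samples) && all(c("m_occ", "m_occder", "m_intact") %in% names(samples))) {
    purrr::pmap(list(samples$m_occ, samples$m_occder, samples$m_intact),
                function(a, b, c) list(m_occ_s = a, m_occder_s = b, m_intact_s = c))
  } else if (is.list(samples)) {
    samples
  } else {
    abort("unsupported sample container")
  }
  if (length(items) == 0) abort("sample stream is empty")
  if (is.null(model)) {
    model <- amodal_unet(input_size, depth, base, seed = derive_seed(seed, 0L))
  }
  size <- model$cfg$input_size
  arrs <- lapply(items, sample_arrays, size = size)
  params <- flatten_params(model$net)

  log <- vector("list", iters)
  with_preserved_rng(derive_seed(seed, 1L), {
    running <- NULL
    for (it in seq_len(iters)) {
      idx <- sample.int(length(arrs), batch, replace = TRUE)
      zero_grads(params)
      total <- 0
      for (i in idx) {
        tape_reset()
        a <- arrs[[i]]
        p <- unet_forward(model$net, ag_const(a$x))
        loss <- amodal_loss_node(p, a$target, a$occder, lambda2)
        ag_backward(loss)
        total <- total + loss$value
      }
      tape_reset()
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / batch
      adam_step(params, lr, it, beta1 = beta1, weight_decay = weight_decay)
      mean_loss <- total / batch
      running <- if (is.null(running)) mean_loss else 0.98 * running + 0.02 * mean_loss
      if (it %% log_every == 0 || it == iters) {
        log[[it]] <- tibble::tibble(iteration = it, loss = mean_loss,
                                    running_loss = running)
      }
    }
  })
  model$log <- dplyr::bind_rows(log)
  model$trained <- TRUE
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training log of an amodal model
#'
#' @param x A trained `amodal_model`.
#' @param ... Unused.
#' @return The training log tibble.
#' @export
tidy.amodal_model <- function(x, ...) {
  if (is.null(x$log)) tibble::tibble(iteration = integer(), loss = numeric(),
                                     running_loss = numeric()) else x$log
}

#' @rdname tidy.amodal_model
#' @return `glance()`: a one-row summary tibble.
#' @export
glance.amodal_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$net), function(p) length(p$value), numeric(1)))
  tibble::tibble(
    input_size = x$cfg$input_size, depth = x$cfg$depth, base = x$cfg$base,
    n_parameters = np, trained = x$trained,
    iterations = if (is.null(x$log)) 0L else max(x$log$iteration),
    final_loss = if (is.null(x$log)) NA_real_ else dplyr::last(x$log$running_loss)
  )
}

# ---- evaluation and the occlusion-relation rule -----------------------------

#' Evaluate completion quality over held-out occlusion pairs
#'
#' For every pair, measures the amodal IoU of the visible mask against the
#' ground-truth complete mask (`before`) and of the model's prediction
#' against it (`after`).
#'
#' @param model A trained `amodal_model` (or a function
#'   `(m_occ, m_occder) -> mask` used as the completer).
#' @param pairs A tibble with list-columns `m_occ`, `m_occder`, `m_intact`.
#' @return `pairs` with numeric columns `iou_before`, `iou_after` added.
#' @export
evaluate_completion <- function(model, pairs) {
  completer <- as_completer(model)
  res <- purrr::pmap_dfr(
    list(pairs$m_occ, pairs$m_occder, pairs$m_intact),
    function(mo, md, mi) {
      size <- if (inherits(model, "amodal_model")) model$cfg$input_size else nrow(mi)
      mo <- fit_to_model(mo, size); md <- fit_to_model(md, size)
      mi <- fit_to_model(mi, size)
      pred <- completer(mo, md)
      tibble::tibble(
        iou_before = amodal_iou(mi, mo)$value,
        iou_after = amodal_iou(mi, pred)$value
      )
    }
  )
  dplyr::bind_cols(pairs, res)
}

as_completer <- function(model) {
  if (inherits(model, "amodal_model")) {
    function(m, m_other) amodal_forward(model, m, m_other)$m_a
  } else if (is.function(model)) {
    model
  } else {
    abort("model must be an amodal_model or a completer function")
  }
}

# relative area growth of one instance under cross-prediction
area_growth <- function(completer, m, m_other, size = NULL) {
  if (!is.null(size)) { m <- fit_to_model(m, size); m_other <- fit_to_model(m_other, size) }
  ma <- completer(m, m_other)
  (mask_area(ma) - mask_area(m)) / mask_area(m)
}

#' Decide the occlusion relationship of an instance pair
#'
#' Cross-predicts amodal masks for the pair — `f(m_i, m_j)` and
#' `f(m_j, m_i)` — and compares the relative mask-area growths
#' `delta = (|amodal| - |visible|) / |visible|`. Both growths at or below
#' `tau` mean no occlusion (`o = -1`); otherwise the instance that grew
#' more is the occluded one: `o = 1` when `m_j` occludes `m_i`
#' (`delta_i > delta_j`), `o = 0` for the inverse. Equal growths above
#' `tau` (outside the rule's three branches) are recorded as `o = 0` with
#' `ambiguous = TRUE`.
#'
#' @param m_i,m_j Nonempty visible masks of the pair, equal shapes.
#' @param model A trained `amodal_model` or completer function.
#' @param tau Near-zero tolerance on the area growth (default 0.01).
#' @return A one-row tibble: `o`, `delta_i`, `delta_j`, `ambiguous`.
#' @export
occlusion_relation <- function(m_i, m_j, model, tau = 0.01) {
  m_i <- as_mask(m_i); m_j <- as_mask(m_j)
  check_same_shape(m_i, m_j)
  if (mask_area(m_i) == 0 || mask_area(m_j) == 0) {
    abort("both masks must be nonempty")
  }
  completer <- as_completer(model)
  size <- if (inherits(model, "amodal_model")) model$cfg$input_size else NULL
  di <- area_growth(completer, m_i, m_j, size)
  dj <- area_growth(completer, m_j, m_i, size)
  if (di <= tau && dj <= tau) {
    o <- -1L; amb <- FALSE
  } else if (di > dj) {
    o <- 1L; amb <- FALSE
  } else if (dj > di) {
    o <- 0L; amb <- FALSE
  } else {
    o <- 0L; amb <- TRUE
  }
  tibble::tibble(o = o, delta_i = di, delta_j = dj, ambiguous = amb)
}

#' Pair instances whose bounding boxes overlap
#'
#' @param masks A list of binary masks sharing one frame.
#' @return A tibble with columns `i`, `j` (`i < j`), one row per unordered
#'   pair of instances with intersecting tight bounding boxes.
#' @export
pair_instances <- function(masks) {
  boxes <- lapply(masks, mask_bbox)
  n <- length(masks)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (is.null(boxes[[i]]) || is.null(boxes[[j]])) next
        if (bbox_intersects(boxes[[i]], boxes[[j]])) {
          out[[length(out) + 1]] <- tibble::tibble(i = i, j = j)
        }
      }
    }
  }
  if (length(out) == 0) tibble::tibble(i = integer(), j = integer())
  else dplyr::bind_rows(out)
}

# ---- checkpointing ----------------------------------------------------------

#' Save or load amodal model weights
#'
#' Checkpoints are plain JSON (weights flattened with dimensions), so they
#' are portable and diffable.
#'
#' @param model An `amodal_model`.
#' @param path Checkpoint path.
#' @return `save_amodal_model` returns `path` invisibly; `load_amodal_model`
#'   returns the restored model.
#' @export
save_amodal_model <- function(model, path) {
  params <- flatten_params(model$net)
  payload <- list(
    cfg = model$cfg,
    weights = lapply(params, function(p) {
      list(dim = dim(p$value) %||% length(p$value), value = as.numeric(p$value))
    })
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' @rdname save_amodal_model
#' @export
load_amodal_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cfg <- payload$cfg
  model <- amodal_unet(cfg$input_size, cfg$depth, cfg$base, seed = cfg$seed)
  params <- flatten_params(model$net)
  stopifnot(length(params) == length(payload$weights))
  for (i in seq_along(params)) {
    wi <- payload$weights[[i]]
    v <- as.numeric(unlist(wi$value))
    d <- as.integer(unlist(wi$dim))
    params[[i]]$value <- if (length(d) > 1) array(v, d) else v
  }
  model$trained <- TRUE
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
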