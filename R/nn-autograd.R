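# A minimal reverse-mode autograd engine for the package's two small
# networks (the dual-decoder heads and the U-Net mask completer). Tensors
# are single-sample arrays (h, w, c); nodes are environments holding value,
# grad and a backward closure; a per-forward tape records creation order
# and backward() walks it in reverse. Convolution kernels live in
# src/nn_ops.cpp.

.tape <- new.env(parent = emptyenv())
.tape$nodes <- list()
.tape$enabled <- TRUE

tape_reset <- function() .tape$nodes <- list()

new_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$requires_grad <- any(vapply(parents, function(p) p$requires_grad, logical(1)))
  if (n$requires_grad && !is.null(backward) && isTRUE(.tape$enabled)) {
    .tape$nodes[[length(.tape$nodes) + 1L]] <- n
  }
  n
}

new_param <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- list()
  n$backward <- NULL
  n$requires_grad <- TRUE
  n$is_param <- TRUE
  n
}

ag_const <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- list()
  n$backward <- NULL
  n$requires_grad <- FALSE
  n
}

accum <- function(p, g) {
  if (!p$requires_grad) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the current tape.
ag_backward <- function(loss) {
  loss$grad <- 1
  nodes <- .tape$nodes
  for (i in rev(seq_along(nodes))) {
    n <- nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n$grad, n)
  }
  invisible(NULL)
}

# ---- tensor ops -------------------------------------------------------------

op_conv <- function(x, W, b, stride = 1L, pad = 1L) {
  k <- dim(W$value)[1]
  y <- conv2d_fwd_cpp(x$value, W$value, b$value, k, stride, pad)
  new_node(y, list(x, W, b), function(g, node) {
    r <- conv2d_bwd_cpp(x$value, W$value, g, k, stride, pad)
    accum(x, r$dx); accum(W, r$dW); accum(b, as.numeric(r$db))
  })
}

op_convt2 <- function(x, W, b) {
  y <- convt2_fwd_cpp(x$value, W$value, b$value)
  new_node(y, list(x, W, b), function(g, node) {
    r <- convt2_bwd_cpp(x$value, W$value, g)
    accum(x, r$dx); accum(W, r$dW); accum(b, as.numeric(r$db))
  })
}

op_maxpool2 <- function(x) {
  r <- maxpool2_fwd_cpp(x$value)
  h <- dim(x$value)[1]; w <- dim(x$value)[2]
  new_node(r$y, list(x), function(g, node) {
    accum(x, maxpool2_bwd_cpp(r$idx, g, h, w))
  })
}

op_relu <- function(x) {
  mask <- x$value > 0
  new_node(x$value * mask, list(x), function(g, node) accum(x, g * mask))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  new_node(s, list(x), function(g, node) accum(x, g * s * (1 - s)))
}

op_add <- function(x, y) {
  new_node(x$value + y$value, list(x, y), function(g, node) {
    accum(x, g); accum(y, g)
  })
}

op_sub <- function(x, y) {
  new_node(x$value - y$value, list(x, y), function(g, node) {
    accum(x, g); accum(y, -g)
  })
}

op_mul <- function(x, y) {
  new_node(x$value * y$value, list(x, y), function(g, node) {
    accum(x, g * y$value); accum(y, g * x$value)
  })
}

# elementwise product with a constant raster (e.g. a supervision mask)
op_mul_const <- function(x, m) {
  m <- as.numeric(m)
  new_node(x$value * m, list(x), function(g, node) accum(x, g * m))
}

op_concat_c <- function(x, y) {
  dx <- dim(x$value); dy2 <- dim(y$value)
  v <- array(c(x$value, y$value), c(dx[1], dx[2], dx[3] + dy2[3]))
  new_node(v, list(x, y), function(g, node) {
    accum(x, g[, , seq_len(dx[3]), drop = FALSE])
    accum(y, g[, , dx[3] + seq_len(dy2[3]), drop = FALSE])
  })
}

op_slice_c <- function(x, idx) {
  d <- dim(x$value)
  new_node(x$value[, , idx, drop = FALSE], list(x), function(g, node) {
    dx <- array(0, d)
    dx[, , idx] <- g
    accum(x, dx)
  })
}

# global average pool: (h, w, c) -> length-c vector
op_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  v <- colMeans(matrix(x$value, hw, d[3]))
  new_node(v, list(x), function(g, node) {
    accum(x, array(rep(g, each = hw) / hw, d))
  })
}

op_dense <- function(v, W, b) {
  y <- as.numeric(W$value %*% v$value + b$value)
  new_node(y, list(v, W, b), function(g, node) {
    accum(v, as.numeric(crossprod(W$value, g)))
    accum(W, outer(g, v$value))
    accum(b, g)
  })
}

# broadcast a length-c vector over channels of (h, w, c)
op_scale_c <- function(x, s) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  srep <- array(rep(s$value, each = hw), d)
  new_node(x$value * srep, list(x, s), function(g, node) {
    accum(x, g * srep)
    accum(s, colSums(matrix(g * x$value, hw, d[3])))
  })
}

# ---- scalar losses ----------------------------------------------------------

# mean binary cross-entropy with probabilities clamped to [eps, 1 - eps]
op_bce <- function(p, target, eps = 1e-7) {
  t <- as.numeric(if (is.numeric(target)) target else target$value)
  pc <- pmin(pmax(p$value, eps), 1 - eps)
  n <- length(pc)
  val <- mean(-t * log(pc) - (1 - t) * log(1 - pc))
  new_node(val, list(p), function(g, node) {
    inside <- (p$value > eps) & (p$value < 1 - eps)
    accum(p, g * inside * (pc - t) / (pc * (1 - pc)) / n)
  })
}

# dice loss with +1 smoothing: 1 - (2*sum(p*t) + 1) / (sum(p^2) + sum(t^2) + 1)
op_dice <- function(p, target) {
  t <- as.numeric(if (is.numeric(target)) target else target$value)
  a <- 2 * sum(p$value * t) + 1
  b <- sum(p$value^2) + sum(t^2) + 1
  new_node(1 - a / b, list(p), function(g, node) {
    accum(p, g * (2 * p$value * a - 2 * t * b) / b^2)
  })
}

sc_add <- function(x, y) {
  new_node(x$value + y$value, list(x, y), function(g, node) {
    accum(x, g); accum(y, g)
  })
}

sc_mul <- function(x, k) {
  new_node(x$value * k, list(x), function(g, node) accum(x, g * k))
}

# ---- parameter helpers and optimizer ----------------------------------------

init_conv_param <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  list(
    W = new_param(array(stats::rnorm(k * k * cin * cout, 0, sd),
                        c(k, k, cin, cout))),
    b = new_param(numeric(cout))
  )
}

init_dense_param <- function(n_in, n_out) {
  sd <- sqrt(2 / n_in)
  list(
    W = new_param(matrix(stats::rnorm(n_out * n_in, 0, sd), n_out, n_in)),
    b = new_param(numeric(n_out))
  )
}

flatten_params <- function(x) {
  if (is.environment(x)) return(list(x))
  if (!is.list(x)) return(list())
  unlist(lapply(x, flatten_params), recursive = FALSE, use.names = FALSE)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Adam with decoupled-from-nothing classic L2 weight decay (grad + wd * w).
adam_step <- function(params, lr, step, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) {
      if (weight_decay == 0) next
      g <- 0 * p$value
    }
    g <- g + weight_decay * p$value
    if (is.null(p$m)) { p$m <- 0 * p$value; p$v <- 0 * p$value }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^step)
    vhat <- p$v / (1 - beta2^step)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# Serialize / restore parameter values (checkpointing).
params_state <- function(params) lapply(params, function(p) p$value)

restore_params <- function(params, state) {
  stopifnot(length(params) == length(state))
  for (i in seq_along(params)) params[[i]]$value <- state[[i]]
  invisible(NULL)
}
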