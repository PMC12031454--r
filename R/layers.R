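# Parameter stores, initialization, and the Adam optimizer.
#
# A model's learnable state lives in a param store: an environment mapping
# parameter names to numeric arrays, plus Adam moment estimates. Forward
# passes lift parameters onto the tape with ag_use_param(); after
# ag_backward(), collect_grads() sums gradients by name (a parameter used at
# several tape positions, e.g. the shared attention MLP, accumulates).

param_store <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$m <- list()
  e$v <- list()
  e$t <- 0L
  e
}

# Glorot-style uniform fan-based initialization. For convolution kernels
# (kh, kw, cin, cout) the fans are kh*kw*cin and kh*kw*cout; for dense
# matrices (cin, cout) they are the two dims. Biases start at zero.
glorot_init <- function(dim) {
  if (length(dim) == 4L) {
    fan_in <- dim[1L] * dim[2L] * dim[3L]
    fan_out <- dim[1L] * dim[2L] * dim[4L]
  } else if (length(dim) == 2L) {
    fan_in <- dim[1L]
    fan_out <- dim[2L]
  } else {
    fan_in <- fan_out <- prod(dim)
  }
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}

add_param <- function(store, name, dim, init = c("glorot", "zero")) {
  init <- match.arg(init)
  store$params[[name]] <- if (init == "glorot") glorot_init(dim) else
    array(0, dim = dim)
  invisible(store)
}

ag_use_param <- function(tape, store, name) {
  p <- store$params[[name]]
  if (is.null(p)) stop("unknown parameter: ", name)
  ag_node(tape, p, pname = name)
}

collect_grads <- function(tape) {
  grads <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$pname) && !is.null(nd$grad)) {
      g <- nd$grad
      if (is.null(grads[[nd$pname]])) grads[[nd$pname]] <- g else
        grads[[nd$pname]] <- grads[[nd$pname]] + g
    }
  }
  grads
}

adam_step <- function(store, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  store$t <- store$t + 1L
  bc1 <- 1 - beta1^store$t
  bc2 <- 1 - beta2^store$t
  for (name in names(grads)) {
    g <- grads[[name]]
    dim(g) <- dim(store$params[[name]])
    if (is.null(store$m[[name]])) {
      store$m[[name]] <- store$params[[name]] * 0
      store$v[[name]] <- store$params[[name]] * 0
    }
    store$m[[name]] <- beta1 * store$m[[name]] + (1 - beta1) * g
    store$v[[name]] <- beta2 * store$v[[name]] + (1 - beta2) * g^2
    mhat <- store$m[[name]] / bc1
    vhat <- store$v[[name]] / bc2
    store$params[[name]] <- store$params[[name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(store)
}

# flat copy of a store (for checkpointing)
store_to_list <- function(store) {
  list(params = store$params, m = store$m, v = store$v, t = store$t)
}

store_from_list <- function(x) {
  e <- param_store()
  e$params <- x$params
  e$m <- x$m
  e$v <- x$v
  e$t <- x$t
  e
}
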