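# Reverse-mode automatic differentiation on 3-D feature maps.
#
# A forward pass records every operation on a tape; ag_backward() replays the
# tape in reverse, accumulating gradients into each node's $grad. Feature maps
# are plain numeric arrays with dims (H, W, C); losses are length-1 numerics.
# Nodes are environments so gradient accumulation mutates in place.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

ag_node <- function(tape, value, backfn = NULL, pname = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  nd$pname <- pname
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' @noRd
ag_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

dims3 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("expected an H x W x C array")
  d
}

ag_const <- function(tape, value) ag_node(tape, value)

# ---- arithmetic -------------------------------------------------------------

ag_add <- function(a, b, tape) {
  stopifnot(identical(dim(a$value), dim(b$value)))
  ag_node(tape, a$value + b$value, backfn = function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  })
}

ag_scale <- function(a, s, tape) {
  ag_node(tape, a$value * s, backfn = function(g) ag_accum(a, g * s))
}

# multiply an (H, W, C) map by channel weights (1, 1, C), broadcasting over
# pixels
ag_mul_channel <- function(f, wc, tape) {
  d <- dims3(f$value)
  stopifnot(identical(dims3(wc$value), c(1L, 1L, d[3L])))
  wvec <- as.vector(wc$value)
  wexp <- array(rep(wvec, each = d[1L] * d[2L]), dim = d)
  ag_node(tape, f$value * wexp, backfn = function(g) {
    ag_accum(f, g * wexp)
    gw <- colSums(matrix(g * f$value, ncol = d[3L]))
    ag_accum(wc, array(gw, dim = c(1L, 1L, d[3L])))
  })
}

# multiply an (H, W, C) map by spatial weights (H, W, 1), broadcasting over
# channels
ag_mul_spatial <- function(f, ws, tape) {
  d <- dims3(f$value)
  stopifnot(identical(dims3(ws$value), c(d[1L], d[2L], 1L)))
  wexp <- array(as.vector(ws$value), dim = d)
  ag_node(tape, f$value * wexp, backfn = function(g) {
    ag_accum(f, g * wexp)
    gs <- rowSums(matrix(g * f$value, ncol = d[3L]))
    ag_accum(ws, array(gs, dim = c(d[1L], d[2L], 1L)))
  })
}

# ---- activations ------------------------------------------------------------

ag_relu <- function(a, tape) {
  v <- a$value
  mask <- v > 0
  v[!mask] <- 0
  ag_node(tape, v, backfn = function(g) ag_accum(a, g * mask))
}

ag_sigmoid <- function(a, tape) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(tape, s, backfn = function(g) ag_accum(a, g * s * (1 - s)))
}

# ---- convolution and pooling ------------------------------------------------

ag_conv2d <- function(x, w, b, tape) {
  y <- cpp_conv2d_fwd(x$value, w$value, as.vector(b$value))
  ag_node(tape, y, backfn = function(g) {
    gr <- cpp_conv2d_bwd(x$value, w$value, g)
    ag_accum(x, gr$gx)
    ag_accum(w, gr$gw)
    ag_accum(b, gr$gb)
  })
}

ag_maxpool2 <- function(x, tape) {
  d <- dims3(x$value)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
    stop("max-pooling requires even height and width, got ", d[1L], "x", d[2L])
  }
  r <- cpp_maxpool2_fwd(x$value)
  nd <- ag_node(tape, r$y, backfn = function(g) {
    ag_accum(x, cpp_maxpool2_bwd(g, r$idx, d[1L], d[2L], d[3L]))
  })
  nd$pool_idx <- r$idx
  nd$pool_dims <- d
  nd
}

# unpool x to the geometry recorded by pool_node (a node made by ag_maxpool2)
ag_unpool2 <- function(x, pool_node, tape) {
  d <- pool_node$pool_dims
  dx <- dims3(x$value)
  stopifnot(identical(dx, dims3(pool_node$value)))
  y <- cpp_unpool2_fwd(x$value, pool_node$pool_idx, d[1L], d[2L], d[3L])
  ag_node(tape, y, backfn = function(g) {
    ag_accum(x, cpp_unpool2_bwd(g, pool_node$pool_idx, dx[1L], dx[2L], dx[3L]))
  })
}

# nearest-neighbour x2 upsampling
ag_upsample2 <- function(x, tape) {
  d <- dims3(x$value)
  y <- x$value[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
               drop = FALSE]
  ag_node(tape, y, backfn = function(g) {
    o1 <- seq(1L, 2L * d[1L], by = 2L)
    o2 <- seq(1L, 2L * d[2L], by = 2L)
    gx <- g[o1, o2, , drop = FALSE] + g[o1 + 1L, o2, , drop = FALSE] +
      g[o1, o2 + 1L, , drop = FALSE] + g[o1 + 1L, o2 + 1L, , drop = FALSE]
    ag_accum(x, gx)
  })
}

# ---- global and along-channel pooling ---------------------------------------

# global average pool -> (1, 1, C)
ag_gap <- function(x, tape) {
  d <- dims3(x$value)
  np <- d[1L] * d[2L]
  v <- colMeans(matrix(x$value, ncol = d[3L]))
  ag_node(tape, array(v, dim = c(1L, 1L, d[3L])), backfn = function(g) {
    gvec <- as.vector(g)
    ag_accum(x, array(rep(gvec / np, each = np), dim = d))
  })
}

# global max pool -> (1, 1, C)
ag_gmp <- function(x, tape) {
  d <- dims3(x$value)
  np <- d[1L] * d[2L]
  m <- matrix(x$value, ncol = d[3L])
  arg <- integer(d[3L])
  v <- numeric(d[3L])
  for (c in seq_len(d[3L])) {
    arg[c] <- which.max(m[, c])
    v[c] <- m[arg[c], c]
  }
  ag_node(tape, array(v, dim = c(1L, 1L, d[3L])), backfn = function(g) {
    gx <- array(0, dim = d)
    gx[arg + (seq_len(d[3L]) - 1L) * np] <- as.vector(g)
    ag_accum(x, gx)
  })
}

# per-pixel mean along channels -> (H, W, 1)
ag_chmean <- function(x, tape) {
  d <- dims3(x$value)
  v <- rowMeans(matrix(x$value, ncol = d[3L]))
  ag_node(tape, array(v, dim = c(d[1L], d[2L], 1L)), backfn = function(g) {
    ag_accum(x, array(as.vector(g) / d[3L], dim = d))
  })
}

# per-pixel max along channels -> (H, W, 1)
ag_chmax <- function(x, tape) {
  d <- dims3(x$value)
  m <- matrix(x$value, ncol = d[3L])
  arg <- max.col(m, ties.method = "first")
  np <- d[1L] * d[2L]
  pick <- seq_len(np) + (arg - 1L) * np
  ag_node(tape, array(m[pick], dim = c(d[1L], d[2L], 1L)), backfn = function(g) {
    gx <- array(0, dim = d)
    gx[pick] <- as.vector(g)
    ag_accum(x, gx)
  })
}

ag_concat_c <- function(a, b, tape) {
  da <- dims3(a$value)
  db <- dims3(b$value)
  stopifnot(da[1L] == db[1L], da[2L] == db[2L])
  y <- array(c(a$value, b$value), dim = c(da[1L], da[2L], da[3L] + db[3L]))
  ag_node(tape, y, backfn = function(g) {
    ag_accum(a, g[, , seq_len(da[3L]), drop = FALSE])
    ag_accum(b, g[, , da[3L] + seq_len(db[3L]), drop = FALSE])
  })
}

# ---- dense layer on (1, 1, C) vectors ---------------------------------------

ag_dense <- function(v, w, b, tape) {
  x <- as.vector(v$value)
  stopifnot(length(x) == nrow(w$value))
  y <- as.vector(crossprod(w$value, x)) + as.vector(b$value)
  ag_node(tape, array(y, dim = c(1L, 1L, length(y))), backfn = function(g) {
    gv <- as.vector(g)
    ag_accum(v, array(as.vector(w$value %*% gv), dim = dim(v$value)))
    ag_accum(w, outer(x, gv))
    ag_accum(b, gv)
  })
}

# ---- per-pixel softmax over channels ----------------------------------------

ag_softmax_c <- function(x, tape) {
  d <- dims3(x$value)
  m <- matrix(x$value, ncol = d[3L])
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  ag_node(tape, array(p, dim = d), backfn = function(g) {
    gm <- matrix(g, ncol = d[3L])
    dot <- rowSums(gm * p)
    ag_accum(x, array(p * (gm - dot), dim = d))
  })
}

# ---- losses -----------------------------------------------------------------

# mean binary cross-entropy between a probability map in (0,1) and a 0/1 mask;
# probabilities are clipped to [eps, 1-eps] before the logs
ag_bce <- function(pred, truth, tape, eps = 1e-7) {
  t <- as.numeric(truth)
  p <- pmin(pmax(as.numeric(pred$value), eps), 1 - eps)
  n <- length(p)
  loss <- -mean(t * log(p) + (1 - t) * log(1 - p))
  ag_node(tape, loss, backfn = function(g) {
    gp <- g * (p - t) / (p * (1 - p)) / n
    ag_accum(pred, array(gp, dim = dim(pred$value)))
  })
}

# soft Jaccard loss over the classes present in the truth tile; classes with no
# truth pixels are excluded from the mean. With an entirely empty label the
# loss falls back to categorical cross-entropy against class 0.
ag_filtered_jaccard <- function(pred, truth, tape, eps = 1e-7) {
  d <- dims3(pred$value)
  K <- d[3L]
  np <- d[1L] * d[2L]
  t <- as.integer(truth)
  if (length(t) != np) stop("truth geometry does not match prediction")
  if (length(t) > 0 && (min(t) < 0L || max(t) >= K)) {
    stop("truth labels must lie in 0..", K - 1L)
  }
  p <- matrix(pred$value, ncol = K)
  onehot <- matrix(0, nrow = np, ncol = K)
  onehot[cbind(seq_len(np), t + 1L)] <- 1
  present <- which(tabulate(t + 1L, nbins = K) > 0L)
  if (length(present) == 0L) {
    loss <- -mean(log(pmax(p[, 1L], eps)))
    return(ag_node(tape, loss, backfn = function(g) {
      gp <- matrix(0, nrow = np, ncol = K)
      gp[, 1L] <- -g / (np * pmax(p[, 1L], eps))
      ag_accum(pred, array(gp, dim = d))
    }))
  }
  inter <- colSums(p * onehot)
  union <- colSums(p) + colSums(onehot) - inter
  jac <- inter / union
  loss <- 1 - mean(jac[present])
  ag_node(tape, loss, backfn = function(g) {
    gp <- matrix(0, nrow = np, ncol = K)
    for (k in present) {
      # d/dp of I/U with dI/dp = t, dU/dp = 1 - t
      gp[, k] <- -(g / length(present)) *
        (onehot[, k] * union[k] - inter[k] * (1 - onehot[, k])) / union[k]^2
    }
    ag_accum(pred, array(gp, dim = d))
  })
}
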