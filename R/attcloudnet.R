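#' AttCloudNet+ configuration
#'
#' AttCloudNet+ is a deeper encoder-decoder for mangrove species
#' identification. Each contracting stage sums a three-convolution branch
#' with a parallel 1x1 branch and max-pools the sum; a feedforward path pools
#' every stage's pre-pool sum to the bottleneck geometry and accumulates
#' them; an expanding step convolves the feedforward result twice and adds
#' the bottleneck; upsampling stages restore the input geometry; a K-class
#' softmax head labels every pixel. Parallel dual attention can be inserted
#' at the bottleneck, between downsampling and upsampling (see
#' [insert_attention_bottleneck()]).
#'
#' @param input_channels Number of raster bands.
#' @param n_classes Number of output classes (4 for the species task:
#'   0 Aegiceras corniculatum-Avicennia marina, 1 Rhizophora stylosa,
#'   2 Sonneratia apetala, 3 other).
#' @param depth Number of contracting stages; tile sides must be divisible by
#'   `2^depth`.
#' @param widths Per-stage channel widths (length `depth`). Defaults to
#'   c(16, 32, 64, 128); tests use c(4, 8, 16, 32).
#' @param attention An [attention_config()] used if attention is inserted.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `attcloudnet_config`.
#' @export
attcloudnet_config <- function(input_channels = 5L, n_classes = 4L,
                               depth = 4L, widths = c(16L, 32L, 64L, 128L),
                               attention = attention_config(), seed = 1L) {
  depth <- as.integer(depth)
  widths <- as.integer(widths)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (length(widths) != depth || any(widths < 1L)) {
    stop("widths must be ", depth, " positive integers")
  }
  structure(list(input_channels = as.integer(input_channels),
                 n_classes = n_classes, depth = depth, widths = widths,
                 attention = attention, seed = as.integer(seed)),
            class = "attcloudnet_config")
}

#' Build an AttCloudNet+ model (without bottleneck attention)
#'
#' @param cfg An [attcloudnet_config()].
#' @return An object of class `attcloudnet`. Call
#'   [insert_attention_bottleneck()] to add the dual-attention block.
#' @export
build_attcloudnet <- function(cfg) {
  stopifnot(inherits(cfg, "attcloudnet_config"))
  st <- param_store()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  w <- cfg$widths
  D <- cfg$depth
  conv <- function(name, k, ci, co) {
    add_param(st, paste0(name, "_w"), c(k, k, ci, co))
    add_param(st, paste0(name, "_b"), co, init = "zero")
  }
  for (i in seq_len(D)) {
    ci <- if (i == 1L) cfg$input_channels else w[i - 1L]
    conv(paste0("c", i, "a"), 3L, ci, w[i])
    conv(paste0("c", i, "b"), 3L, w[i], w[i])
    conv(paste0("c", i, "c"), 3L, w[i], w[i])
    conv(paste0("c", i, "p"), 1L, ci, w[i])
    conv(paste0("ffproj", i), 1L, w[i], w[D])
  }
  conv("exp1", 3L, w[D], w[D])
  conv("exp2", 3L, w[D], w[D])
  for (i in seq_len(D)) {
    co <- if (i == 1L) w[1L] else w[i - 1L]
    conv(paste0("up", i), 3L, w[i], co)
    # 1x1 lateral projection of the contracting skip into the decoder level
    conv(paste0("dproj", i), 1L, w[i], co)
  }
  conv("head", 1L, w[1L], cfg$n_classes)
  structure(list(cfg = cfg, store = st, attention = FALSE),
            class = "attcloudnet")
}

#' Insert parallel dual attention at the bottleneck
#'
#' Adds a parallel dual-attention block acting on the deepest encoding,
#' applied after the last contracting stage and before the expanding path.
#' With the attention parameters at zero the block's weights are all exactly
#' 0.5 and the forward pass equals the unaugmented model.
#'
#' @param model An [build_attcloudnet()] model.
#' @return The model with attention enabled.
#' @export
insert_attention_bottleneck <- function(model) {
  stopifnot(inherits(model, "attcloudnet"))
  if (!model$attention) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(model$cfg$seed + 1L)
    add_attention_params(model$store, "attb",
                         model$cfg$widths[model$cfg$depth],
                         model$cfg$attention)
    model$attention <- TRUE
  }
  model
}

forward_attcloudnet <- function(model, xnorm, tape) {
  st <- model$store
  cfg <- model$cfg
  D <- cfg$depth
  d <- dims3(xnorm)
  if (d[3L] != cfg$input_channels) {
    stop("expected ", cfg$input_channels, " bands, got ", d[3L])
  }
  if (d[1L] %% 2L^D != 0L || d[2L] %% 2L^D != 0L) {
    stop("tile sides must be divisible by ", 2L^D)
  }
  cur <- ag_const(tape, xnorm)
  skips <- vector("list", D)
  for (i in seq_len(D)) {
    b3 <- ag_relu(ag_conv_named(tape, st, paste0("c", i, "a"), cur), tape)
    b3 <- ag_relu(ag_conv_named(tape, st, paste0("c", i, "b"), b3), tape)
    b3 <- ag_conv_named(tape, st, paste0("c", i, "c"), b3)
    b1 <- ag_conv_named(tape, st, paste0("c", i, "p"), cur)
    s <- ag_add(b3, b1, tape)
    skips[[i]] <- s
    cur <- ag_maxpool2(s, tape)
  }
  bott <- cur
  if (isTRUE(model$attention)) {
    pn <- lift_store_params(tape, st, "attb", ATT_PARAM_NAMES)
    bott <- ag_parallel_attention(tape, bott, pn)
  }
  # feedforward path: project each skip to the deepest width, pool to the
  # bottleneck geometry, accumulate
  ff <- NULL
  for (i in seq_len(D)) {
    p <- ag_conv_named(tape, st, paste0("ffproj", i), skips[[i]])
    for (k in seq_len(D - i + 1L)) p <- ag_maxpool2(p, tape)
    ff <- if (is.null(ff)) p else ag_add(ff, p, tape)
  }
  e <- ag_conv_named(tape, st, "exp2",
                     ag_relu(ag_conv_named(tape, st, "exp1", ff), tape))
  u <- ag_add(e, bott, tape)
  for (i in seq(D, 1L)) {
    u <- ag_upsample2(u, tape)
    u <- ag_add(ag_relu(ag_conv_named(tape, st, paste0("up", i), u), tape),
                ag_conv_named(tape, st, paste0("dproj", i), skips[[i]]), tape)
  }
  logits <- ag_conv_named(tape, st, "head", u)
  ag_softmax_c(logits, tape)
}

# ---- exported block-level operations ---------------------------------------

#' Initialize contracting-block parameters
#'
#' @param input_channels Channels of the incoming feature map.
#' @param width Output channel width of the block.
#' @return Named list of kernels/biases for the three successive 3x3
#'   convolutions (`w1..w3`, `b1..b3`) and the parallel 1x1 convolution
#'   (`wp`, `bp`).
#' @export
contracting_params <- function(input_channels, width) {
  list(w1 = glorot_init(c(3L, 3L, input_channels, width)), b1 = numeric(width),
       w2 = glorot_init(c(3L, 3L, width, width)), b2 = numeric(width),
       w3 = glorot_init(c(3L, 3L, width, width)), b3 = numeric(width),
       wp = glorot_init(c(1L, 1L, input_channels, width)), bp = numeric(width))
}

#' Contracting block
#'
#' Runs three successive 3x3 convolutions (rectifier after the first two) and
#' a parallel 1x1 convolution on the same input, sums the two branches, and
#' 2x2 max-pools the sum. The pre-pool sum is returned as the skip
#' connection.
#'
#' @param f Numeric (H, W, C) array with even H and W.
#' @param params A [contracting_params()] list.
#' @return List with `pooled` (H/2, W/2, width) and `skip` (H, W, width).
#' @export
contracting_block <- function(f, params) {
  check_feature_map(f)
  tape <- ag_tape()
  x <- ag_const(tape, f)
  p <- lift_params(tape, params)
  b3 <- ag_relu(ag_conv2d(x, p$w1, p$b1, tape), tape)
  b3 <- ag_relu(ag_conv2d(b3, p$w2, p$b2, tape), tape)
  b3 <- ag_conv2d(b3, p$w3, p$b3, tape)
  b1 <- ag_conv2d(x, p$wp, p$bp, tape)
  s <- ag_add(b3, b1, tape)
  pooled <- ag_maxpool2(s, tape)
  list(pooled = pooled$value, skip = s$value)
}

#' Feedforward block
#'
#' Max-pools each skip connection down to a common geometry (half the side of
#' the smallest skip, i.e. the bottleneck geometry) and accumulates them by
#' summation. All skips must share one channel count; the model projects them
#' with 1x1 convolutions before calling this.
#'
#' @param skips Non-empty list of numeric (H_i, W_i, C) arrays whose sides
#'   are powers of two multiples of the smallest.
#' @return Numeric array at the common pooled geometry.
#' @export
feedforward_block <- function(skips) {
  if (length(skips) == 0L) stop("feedforward block needs at least one skip")
  dims <- lapply(skips, dims3)
  C <- dims[[1L]][3L]
  if (!all(vapply(dims, function(d) d[3L] == C, logical(1L)))) {
    stop("all skips must share one channel count")
  }
  target <- min(vapply(dims, function(d) d[1L], integer(1L))) %/% 2L
  out <- NULL
  for (f in skips) {
    while (dim(f)[1L] > target) f <- cpp_maxpool2_fwd(f)$y
    out <- if (is.null(out)) f else out + f
  }
  out
}

#' Expanding block
#'
#' Convolves the feedforward result twice (3x3, rectifier between) and sums
#' it with the contracting-path input.
#'
#' @param ff Numeric (H, W, C) array from [feedforward_block()].
#' @param contracting Numeric (H, W, C) array from the contracting path.
#' @param params List with kernels `w1`, `w2` (3,3,C,C) and biases `b1`,
#'   `b2`.
#' @return Numeric (H, W, C) array.
#' @export
expanding_block <- function(ff, contracting, params) {
  if (!identical(dims3(ff), dims3(contracting))) {
    stop("expanding block inputs must share geometry")
  }
  h <- cpp_conv2d_fwd(ff, params$w1, as.numeric(params$b1))
  h[h < 0] <- 0
  cpp_conv2d_fwd(h, params$w2, as.numeric(params$b2)) + contracting
}

#' Upsampling block
#'
#' Doubles the geometry by nearest-neighbour replication. Applied once per
#' contracting stage, it restores the network input geometry.
#'
#' @param f Numeric (H, W, C) array.
#' @return Numeric (2H, 2W, C) array.
#' @export
upsampling_block <- function(f) {
  d <- dims3(f)
  f[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

#' Filtered Jaccard loss
#'
#' One minus the mean soft Jaccard index over the classes present in the
#' ground-truth tile: `J_k = sum(p_k t_k) / (sum p_k + sum t_k - sum(p_k
#' t_k))` on the one-hot expansion of the truth. Classes with no truth pixels
#' are filtered out of the mean, so a tile that lacks a class cannot be
#' penalized for it. If no class is present at all (an empty label) the loss
#' falls back to categorical cross-entropy against the all-background truth.
#'
#' @param pred Numeric (H, W, K) array of per-pixel class probabilities.
#' @param truth Integer (H, W) matrix with labels in `0..K-1`.
#' @return Scalar in `[0, 1]` (when at least one class is present); 0 exactly
#'   when the prediction is one-hot-correct on every present class.
#' @export
filtered_jaccard_loss <- function(pred, truth) {
  tape <- ag_tape()
  ag_filtered_jaccard(ag_const(tape, pred), as_mask_values(truth), tape)$value
}

#' Predict a species mask
#'
#' Per-pixel argmax of the class probability map, with ties broken toward the
#' lowest class index. Classes follow the gray-value convention
#' 0 = Aegiceras corniculatum-Avicennia marina, 1 = Rhizophora stylosa,
#' 2 = Sonneratia apetala, 3 = other.
#'
#' @param model A trained `attcloudnet` model.
#' @param tile A `multispectral_raster` or numeric (H, W, C) array (8-bit
#'   values, normalized internally).
#' @return Integer (H, W) `segmentation_mask` with values in `0..K-1`.
#' @export
predict_species <- function(model, tile) {
  stopifnot(inherits(model, "attcloudnet"))
  probs <- predict_class_probs(model, tile)
  segmentation_mask(argmax_classes(probs))
}

#' Predict per-pixel class probabilities
#'
#' @inheritParams predict_species
#' @return Numeric (H, W, K) array; every pixel's probabilities sum to 1.
#' @export
predict_class_probs <- function(model, tile) {
  tape <- ag_tape()
  forward_attcloudnet(model, normalize_tile(tile), tape)$value
}

# argmax over the channel axis, ties to the lowest class index; returns 0-based
# labels
argmax_classes <- function(probs) {
  d <- dims3(probs)
  lab <- max.col(matrix(probs, ncol = d[3L]), ties.method = "first") - 1L
  matrix(lab, nrow = d[1L], ncol = d[2L])
}
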