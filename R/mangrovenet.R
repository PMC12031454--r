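#' MangroveNet configuration
#'
#' MangroveNet is a deliberately lightweight encoder-decoder for binary
#' mangrove-extent segmentation. The encoder has three convolutional stages
#' (two 3x3 convolutions with rectifier each) separated by exactly two 2x2
#' max-poolings whose argmax indices are recorded; the decoder restores the
#' input geometry by index unpooling. A parallel dual-attention block is
#' attached to each of the three scale views, the attended layers are
#' projected to the base width and fused additively with the un-pooled
#' stage-1 features, and a 1-channel sigmoid head produces the probability
#' map. Tile sides must be divisible by 4 so both unpoolings restore the
#' input geometry.
#'
#' @param input_channels Number of raster bands (5 for B/G/R/RE/NIR).
#' @param stage_widths Integer vector of length 3: channel widths of the
#'   three encoder stages. Defaults to c(64, 128, 256); tests use small
#'   widths such as c(8, 16, 32).
#' @param attention An [attention_config()].
#' @param seed Integer seed controlling parameter initialization.
#' @return An object of class `mangrovenet_config`.
#' @export
mangrovenet_config <- function(input_channels = 5L,
                               stage_widths = c(64L, 128L, 256L),
                               attention = attention_config(),
                               seed = 1L) {
  input_channels <- as.integer(input_channels)
  stage_widths <- as.integer(stage_widths)
  if (input_channels < 1L) stop("input_channels must be positive")
  if (length(stage_widths) != 3L || any(stage_widths < 1L)) {
    stop("stage_widths must be 3 positive integers (two downsamples give three scales)")
  }
  structure(list(input_channels = input_channels, stage_widths = stage_widths,
                 attention = attention, seed = as.integer(seed)),
            class = "mangrovenet_config")
}

#' Build a MangroveNet model
#'
#' Creates the parameter store for the architecture described in
#' [mangrovenet_config()]. Weights are Glorot-uniform, biases zero; the build
#' is a pure function of the config (same seed, same parameters).
#'
#' @param cfg A [mangrovenet_config()].
#' @return An object of class `mangrovenet` holding the config and parameter
#'   store.
#' @export
build_mangrovenet <- function(cfg) {
  stopifnot(inherits(cfg, "mangrovenet_config"))
  w <- cfg$stage_widths
  cin <- cfg$input_channels
  store <- param_store()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  conv <- function(name, k, ci, co) {
    add_param(store, paste0(name, "_w"), c(k, k, ci, co))
    add_param(store, paste0(name, "_b"), co, init = "zero")
  }
  conv("enc1a", 3L, cin, w[1L]); conv("enc1b", 3L, w[1L], w[1L])
  conv("enc2a", 3L, w[1L], w[2L]); conv("enc2b", 3L, w[2L], w[2L])
  conv("enc3a", 3L, w[2L], w[3L]); conv("enc3b", 3L, w[3L], w[3L])
  for (s in 1:3) add_attention_params(store, paste0("att", s), w[s], cfg$attention)
  conv("proj1", 1L, w[1L], w[1L])
  conv("proj2", 1L, w[2L], w[1L])
  conv("proj3", 1L, w[3L], w[1L])
  conv("dec3", 3L, w[3L], w[2L])
  conv("dec2", 3L, w[2L], w[2L])
  conv("dec2to1", 3L, w[2L], w[1L])
  conv("dec1", 3L, w[1L], w[1L])
  conv("head_fused", 1L, w[1L], 1L)
  conv("head_up", 1L, w[1L], 1L)
  structure(list(cfg = cfg, store = store), class = "mangrovenet")
}

# RNG bookkeeping: builds and forward passes must not disturb the caller's
# random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

ag_conv_named <- function(tape, store, name, x) {
  ag_conv2d(x, ag_use_param(tape, store, paste0(name, "_w")),
            ag_use_param(tape, store, paste0(name, "_b")), tape)
}

# full forward pass on one normalized tile; returns the sigmoid output node
forward_mangrovenet <- function(model, xnorm, tape) {
  st <- model$store
  d <- dims3(xnorm)
  if (d[3L] != model$cfg$input_channels) {
    stop("expected ", model$cfg$input_channels, " bands, got ", d[3L])
  }
  if (d[1L] %% 4L != 0L || d[2L] %% 4L != 0L) {
    stop("tile sides must be divisible by 4, got ", d[1L], "x", d[2L])
  }
  x <- ag_const(tape, xnorm)
  a1 <- ag_relu(ag_conv_named(tape, st, "enc1a", x), tape)
  a1 <- ag_relu(ag_conv_named(tape, st, "enc1b", a1), tape)
  p1 <- ag_maxpool2(a1, tape)
  a2 <- ag_relu(ag_conv_named(tape, st, "enc2a", p1), tape)
  a2 <- ag_relu(ag_conv_named(tape, st, "enc2b", a2), tape)
  p2 <- ag_maxpool2(a2, tape)
  a3 <- ag_relu(ag_conv_named(tape, st, "enc3a", p2), tape)
  a3 <- ag_relu(ag_conv_named(tape, st, "enc3b", a3), tape)

  scales <- list(a1, a2, a3)
  fused <- a1   # running sum starts from the un-pooled convolution layer
  for (s in 1:3) {
    pn <- lift_store_params(tape, st, paste0("att", s), ATT_PARAM_NAMES)
    att <- ag_parallel_attention(tape, scales[[s]], pn)
    pr <- ag_conv_named(tape, st, paste0("proj", s), att)
    if (s >= 2L) pr <- ag_upsample2(pr, tape)
    if (s == 3L) pr <- ag_upsample2(pr, tape)
    fused <- ag_add(fused, pr, tape)
  }

  dturn <- ag_relu(ag_conv_named(tape, st, "dec3", a3), tape)
  dturn <- ag_unpool2(dturn, p2, tape)
  dturn <- ag_relu(ag_conv_named(tape, st, "dec2", dturn), tape)
  dturn <- ag_relu(ag_conv_named(tape, st, "dec2to1", dturn), tape)
  dturn <- ag_unpool2(dturn, p1, tape)
  dturn <- ag_relu(ag_conv_named(tape, st, "dec1", dturn), tape)

  logit <- ag_add(ag_conv_named(tape, st, "head_fused", fused),
                  ag_conv_named(tape, st, "head_up", dturn), tape)
  ag_sigmoid(logit, tape)
}

#' Multi-scale additive fusion
#'
#' Upsamples each attended feature layer (nearest-neighbour, doubling as many
#' times as it was pooled) to the geometry of the base layer and accumulates
#' them by running summation starting from the base (the un-pooled
#' convolution layer). All layers must share the base channel count; the
#' model projects each scale with a 1x1 convolution before calling this.
#'
#' @param attended List of numeric (H_s, W_s, C) arrays, one per scale, with
#'   geometries `base/2^k` for integer k >= 0.
#' @param base Numeric (H, W, C) array.
#' @return Numeric (H, W, C) array.
#' @export
fuse_multiscale <- function(attended, base) {
  db <- dims3(base)
  out <- base
  for (f in attended) {
    d <- dims3(f)
    if (d[3L] != db[3L]) stop("channel mismatch in multi-scale fusion")
    while (d[1L] < db[1L]) {
      f <- f[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
             drop = FALSE]
      d <- dims3(f)
    }
    if (!identical(d[1:2], db[1:2])) {
      stop("geometry mismatch after upsampling: ", d[1L], "x", d[2L],
           " vs base ", db[1L], "x", db[2L])
    }
    out <- out + f
  }
  out
}

#' Sigmoid segmentation head
#'
#' Projects the fused multi-scale layer and the final decoder (unpooled)
#' layer each to one channel with a 1x1 convolution, sums them, and applies
#' the sigmoid, yielding a per-pixel probability of the positive (mangrove)
#' class.
#'
#' @param fused Numeric (H, W, C) array: the multi-scale fusion result.
#' @param upsampled_n Numeric (H, W, C2) array: output of the last decoder
#'   unpooling stage.
#' @param params List with 1x1 kernels `w_fused` (1,1,C,1), `w_up`
#'   (1,1,C2,1) and biases `b_fused`, `b_up` (scalars).
#' @return Numeric (H, W, 1) array with values in (0, 1).
#' @export
segmentation_head <- function(fused, upsampled_n, params) {
  d1 <- dims3(fused)
  d2 <- dims3(upsampled_n)
  if (!identical(d1[1:2], d2[1:2])) stop("geometry mismatch in segmentation head")
  z <- cpp_conv2d_fwd(fused, params$w_fused, as.numeric(params$b_fused)) +
    cpp_conv2d_fwd(upsampled_n, params$w_up, as.numeric(params$b_up))
  1 / (1 + exp(-z))
}

#' Binary cross-entropy loss
#'
#' Mean of `-(t log p + (1 - t) log(1 - p))` over all pixels, with
#' probabilities clipped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param pred Numeric array/vector of probabilities in (0, 1).
#' @param truth Numeric array/vector of the same length with values in
#'   \{0, 1\}.
#' @param eps Clipping bound (default 1e-7).
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred, truth, eps = 1e-7) {
  t <- as.numeric(truth)
  if (!all(t %in% c(0, 1))) stop("truth values must be 0 or 1")
  if (length(t) != length(pred)) stop("pred and truth differ in length")
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

# normalize an 8-bit tile to [0,1]
normalize_tile <- function(tile) {
  v <- if (inherits(tile, "multispectral_raster")) tile$values else tile
  v / 255
}

#' Predict a binary extent mask
#'
#' Runs the forward pass on an 8-bit tile (values 0..255, normalized
#' internally by division by 255) and thresholds the probability map; pixels
#' with probability greater than or equal to `threshold` become 1.
#'
#' @param model A trained [build_mangrovenet()] model.
#' @param tile A `multispectral_raster` or numeric (H, W, C) array with sides
#'   divisible by 4 and the configured band count.
#' @param threshold Decision threshold in `[0, 1]` (default 0.5, boundary
#'   inclusive).
#' @return Integer (H, W) matrix of class `segmentation_mask` with values in
#'   \{0, 1\}.
#' @export
predict_mask <- function(model, tile, threshold = 0.5) {
  stopifnot(inherits(model, "mangrovenet"))
  prob <- predict_prob(model, tile)
  segmentation_mask((prob[, , 1L] >= threshold) * 1L)
}

#' Predict the extent probability map
#'
#' @inheritParams predict_mask
#' @return Numeric (H, W, 1) array of probabilities in (0, 1).
#' @export
predict_prob <- function(model, tile) {
  tape <- ag_tape()
  forward_mangrovenet(model, normalize_tile(tile), tape)$value
}
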