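#' Attention configuration
#'
#' Settings for the parallel spectral/spatial attention block. The channel
#' branch squeezes the map through a two-layer shared-weight perceptron whose
#' hidden width is `channels / mlp_reduction_ratio` (floored at 1); the
#' spatial branch convolves the along-channel average/maximum pair with an
#' odd-sized kernel so the weight map keeps the input geometry.
#'
#' @param mlp_reduction_ratio Positive integer; hidden-width reduction of the
#'   channel-attention perceptron.
#' @param spatial_kernel_size Odd positive integer; side of the spatial
#'   attention convolution kernel (default 7).
#' @return An object of class `attention_config`.
#' @export
attention_config <- function(mlp_reduction_ratio = 8L, spatial_kernel_size = 7L) {
  mlp_reduction_ratio <- as.integer(mlp_reduction_ratio)
  spatial_kernel_size <- as.integer(spatial_kernel_size)
  if (mlp_reduction_ratio < 1L) stop("mlp_reduction_ratio must be positive")
  if (spatial_kernel_size < 1L || spatial_kernel_size %% 2L == 0L) {
    stop("spatial_kernel_size must be an odd positive integer")
  }
  structure(list(mlp_reduction_ratio = mlp_reduction_ratio,
                 spatial_kernel_size = spatial_kernel_size),
            class = "attention_config")
}

#' Initialize attention parameters
#'
#' Draws Glorot-uniform weights (zero biases) for one attention block acting
#' on maps with `channels` channels, using the current RNG state. The MLP
#' weights are shared between the average-pool and max-pool branches.
#'
#' @param channels Number of channels of the feature maps the block will see.
#' @param cfg An [attention_config()].
#' @return Named list of arrays: `mlp_w1`, `mlp_b1`, `mlp_w2`, `mlp_b2`
#'   (channel branch) and `conv_w`, `conv_b` (spatial branch).
#' @export
attention_params <- function(channels, cfg = attention_config()) {
  channels <- as.integer(channels)
  if (channels < 1L) stop("channels must be >= 1")
  hid <- max(1L, channels %/% cfg$mlp_reduction_ratio)
  k <- cfg$spatial_kernel_size
  list(mlp_w1 = glorot_init(c(channels, hid)),
       mlp_b1 = numeric(hid),
       mlp_w2 = glorot_init(c(hid, channels)),
       mlp_b2 = numeric(channels),
       conv_w = glorot_init(c(k, k, 2L, 1L)),
       conv_b = numeric(1L))
}

add_attention_params <- function(store, prefix, channels, cfg) {
  p <- attention_params(channels, cfg)
  for (nm in names(p)) {
    store$params[[paste0(prefix, "_", nm)]] <- p[[nm]]
  }
  invisible(store)
}

check_feature_map <- function(f) {
  d <- dims3(f)
  if (d[3L] < 1L) stop("feature map must have at least one channel")
  if (!all(is.finite(f))) stop("feature map contains non-finite values")
  d
}

# param nodes: list with the attention_params() names lifted onto the tape
ag_channel_attention <- function(tape, f, pn) {
  mlp <- function(v) {
    h <- ag_relu(ag_dense(v, pn$mlp_w1, pn$mlp_b1, tape), tape)
    ag_dense(h, pn$mlp_w2, pn$mlp_b2, tape)
  }
  s <- ag_add(mlp(ag_gap(f, tape)), mlp(ag_gmp(f, tape)), tape)
  ag_sigmoid(s, tape)
}

ag_spatial_attention <- function(tape, f, pn) {
  pooled <- ag_concat_c(ag_chmean(f, tape), ag_chmax(f, tape), tape)
  ag_sigmoid(ag_conv2d(pooled, pn$conv_w, pn$conv_b, tape), tape)
}

ag_parallel_attention <- function(tape, f, pn) {
  wc <- ag_channel_attention(tape, f, pn)
  ws <- ag_spatial_attention(tape, f, pn)
  ag_add(ag_mul_channel(f, wc, tape), ag_mul_spatial(f, ws, tape), tape)
}

lift_params <- function(tape, params) {
  lapply(params, function(p) ag_node(tape, p))
}

lift_store_params <- function(tape, store, prefix, names) {
  out <- lapply(names, function(nm) ag_use_param(tape, store, paste0(prefix, "_", nm)))
  names(out) <- names
  out
}

ATT_PARAM_NAMES <- c("mlp_w1", "mlp_b1", "mlp_w2", "mlp_b2", "conv_w", "conv_b")

#' Channel (spectral) attention weights
#'
#' Global average- and max-pools the feature map over space, feeds both pooled
#' vectors through a shared two-layer perceptron with rectifier hidden
#' activation, sums the two outputs elementwise, and applies the logistic
#' sigmoid. The result is one weight per channel, strictly inside (0, 1), and
#' is invariant to any spatial permutation of the input pixels.
#'
#' @param f Numeric array of dims (H, W, C) with finite values.
#' @param cfg An [attention_config()] (kept for interface symmetry; the MLP
#'   widths are read from `params`).
#' @param params Parameter list as produced by [attention_params()].
#' @return Numeric array of dims (1, 1, C) with values in (0, 1).
#' @export
channel_attention <- function(f, cfg = attention_config(), params) {
  check_feature_map(f)
  tape <- ag_tape()
  pn <- lift_params(tape, params)
  ag_channel_attention(tape, ag_const(tape, f), pn)$value
}

#' Spatial attention weights
#'
#' Computes per-pixel average and maximum along the channel axis, concatenates
#' them into a 2-channel map, convolves with an odd-sized kernel under
#' symmetric zero padding (so the geometry is preserved), and applies the
#' sigmoid. The result is one weight per pixel, invariant to any permutation
#' of the input channels.
#'
#' @inheritParams channel_attention
#' @return Numeric array of dims (H, W, 1) with values in (0, 1).
#' @export
spatial_attention <- function(f, cfg = attention_config(), params) {
  check_feature_map(f)
  if (dim(params$conv_w)[1L] %% 2L == 0L) {
    stop("spatial attention kernel must have odd size")
  }
  tape <- ag_tape()
  pn <- lift_params(tape, params)
  ag_spatial_attention(tape, ag_const(tape, f), pn)$value
}

#' Parallel dual attention
#'
#' Applies channel and spatial attention independently to the same input and
#' combines them additively: `Wc * f + Ws * f` with broadcasting over the
#' missing axes. The two branches run in parallel (both see the raw input),
#' unlike serial channel-then-spatial designs.
#'
#' @inheritParams channel_attention
#' @return Numeric array with the same dims as `f`.
#' @export
parallel_dual_attention <- function(f, cfg = attention_config(), params) {
  check_feature_map(f)
  tape <- ag_tape()
  pn <- lift_params(tape, params)
  ag_parallel_attention(tape, ag_const(tape, f), pn)$value
}
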