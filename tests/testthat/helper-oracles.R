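# Independent brute-force oracles used across the suite. All of them are
# straight-line loop implementations kept deliberately separate from the
# package's vectorized/compiled code paths.

# confusion counts by explicit pixel loop
oracle_confusion <- function(truth, pred, K) {
  cm <- matrix(0, K, K)
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(ncol(truth))) {
      cm[truth[i, j] + 1L, pred[i, j] + 1L] <- cm[truth[i, j] + 1L, pred[i, j] + 1L] + 1
    }
  }
  cm
}

# binary metrics as exact integer numerator/denominator pairs
oracle_binary_fractions <- function(cm) {
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  n <- tn + fp + fn + tp
  list(accuracy = c(tp + tn, n),
       precision = c(tp, tp + fp),
       recall = c(tp, tp + fn),
       f1 = c(2 * tp, 2 * tp + fp + fn),
       iou_pos = c(tp, tp + fp + fn),
       iou_neg = c(tn, tn + fn + fp))
}

# kappa as one exact fraction: (N*trace - S) / (N^2 - S)
oracle_kappa_fraction <- function(cm) {
  n <- sum(cm)
  s <- 0
  for (k in seq_len(nrow(cm))) s <- s + sum(cm[k, ]) * sum(cm[, k])
  c(n * sum(diag(cm)) - s, n * n - s)
}

# channel attention by explicit loops, given the same parameters
oracle_channel_attention <- function(f, params) {
  C <- dim(f)[3]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(f[, , c])
    mx[c] <- max(f[, , c])
  }
  mlp <- function(v) {
    h <- as.vector(t(params$mlp_w1) %*% v) + params$mlp_b1
    h[h < 0] <- 0
    as.vector(t(params$mlp_w2) %*% h) + params$mlp_b2
  }
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

# spatial attention by explicit loops (odd kernel, symmetric zero padding)
oracle_spatial_attention <- function(f, params) {
  H <- dim(f)[1]; W <- dim(f)[2]
  k <- dim(params$conv_w)[1]
  p <- (k - 1) / 2
  pooled <- array(0, c(H, W, 2))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    pooled[i, j, 1] <- mean(f[i, j, ])
    pooled[i, j, 2] <- max(f[i, j, ])
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- params$conv_b
    for (ci in 1:2) for (di in seq_len(k)) for (dj in seq_len(k)) {
      ii <- i + di - 1 - p; jj <- j + dj - 1 - p
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        acc <- acc + pooled[ii, jj, ci] * params$conv_w[di, dj, ci, 1]
      }
    }
    out[i, j] <- 1 / (1 + exp(-acc))
  }
  out
}

# Eq-3 combination by scalar loop
oracle_dual_attention <- function(f, wc, ws) {
  out <- array(0, dim = dim(f))
  for (i in seq_len(dim(f)[1])) for (j in seq_len(dim(f)[2])) {
    for (c in seq_len(dim(f)[3])) {
      out[i, j, c] <- wc[1, 1, c] * f[i, j, c] + ws[i, j, 1] * f[i, j, c]
    }
  }
  out
}

# random small mask pair
random_masks <- function(h, w, K, seed) {
  set.seed(seed)
  list(truth = matrix(sample(0:(K - 1), h * w, replace = TRUE), h, w),
       pred = matrix(sample(0:(K - 1), h * w, replace = TRUE), h, w))
}
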