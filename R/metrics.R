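# Evaluation suite: confusion matrices, the five binary indicators
# (accuracy, precision, recall, F1, mIoU), Cohen's kappa with its qualitative
# bands, and overall accuracy.
#
# All metrics are computed from integer pixel counts in single-division
# rational forms (e.g. kappa = (N*trace - S) / (N^2 - S)), so results agree
# exactly with integer-arithmetic oracles. Orientation is fixed as
# rows = truth, columns = prediction throughout; kappa and overall accuracy
# are symmetric in that choice, and the per-class metrics document it.

#' Confusion matrix from a mask pair
#'
#' `counts[i, j]` is the number of pixels with truth class `i-1` and
#' predicted class `j-1` (rows = truth, columns = prediction). The counts sum
#' to the pixel count.
#'
#' @param truth,pred `segmentation_mask`s (or integer matrices) of equal
#'   geometry with labels in `0..K-1`.
#' @param K Number of classes.
#' @param class_names Optional length-K character vector of dimnames.
#' @return K x K integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, K, class_names = NULL) {
  t <- as_mask_values(truth)
  p <- as_mask_values(pred)
  if (!identical(dim(t), dim(p))) stop("truth and pred geometry differ")
  K <- as.integer(K)
  bad <- c(t[t < 0L | t >= K], p[p < 0L | p >= K])
  if (length(bad) > 0L) {
    stop("label ", bad[1L], " outside 0..", K - 1L)
  }
  cm <- matrix(tabulate(as.integer(t) * K + as.integer(p) + 1L, nbins = K * K),
               nrow = K, byrow = TRUE)
  if (!is.null(class_names)) dimnames(cm) <- list(truth = class_names,
                                                  pred = class_names)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

cm_counts <- function(cm) {
  m <- unclass(cm)
  # doubles hold pixel counts exactly (< 2^53) and avoid integer overflow in
  # products like N^2
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || any(m < 0) || sum(m) == 0) {
    stop("confusion matrix must be square, non-negative, with positive total")
  }
  m
}

#' Binary evaluation indicators
#'
#' For a 2x2 confusion matrix with the positive (mangrove) class = 1:
#' accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (the
#' harmonic mean of precision and recall, computed as `2TP/(2TP+FP+FN)`), and
#' the two-class mean intersection-over-union
#' `(TP/(TP+FP+FN) + TN/(TN+FN+FP)) / 2`. A metric whose denominator is zero
#' is reported as 0 and named in the `degenerate` field rather than raising,
#' since degenerate tiles occur routinely in per-tile evaluation.
#'
#' @param cm A 2x2 [confusion_matrix()] (rows = truth, columns = prediction,
#'   class order 0 then 1).
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `miou`,
#'   `kappa`, `kappa_band`, `oa`, and `degenerate` (character vector of
#'   flagged metrics).
#' @export
binary_metrics <- function(cm) {
  m <- cm_counts(cm)
  if (nrow(m) != 2L) stop("binary metrics need a 2x2 matrix")
  tn <- m[1L, 1L]; fp <- m[1L, 2L]; fn <- m[2L, 1L]; tp <- m[2L, 2L]
  n <- tn + fp + fn + tp
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  prec <- safe(tp, tp + fp, "precision")
  rec <- safe(tp, tp + fn, "recall")
  res <- list(
    accuracy = (tp + tn) / n,
    precision = prec,
    recall = rec,
    f1 = safe(2 * tp, 2 * tp + fp + fn, "f1"),
    miou = (safe(tp, tp + fp + fn, "iou_pos") +
              safe(tn, tn + fn + fp, "iou_neg")) / 2,
    kappa = cohen_kappa(cm),
    oa = overall_accuracy(cm)
  )
  res$kappa_band <- kappa_band(res$kappa)
  res$degenerate <- degenerate
  res
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)` with `Po = trace/N` and
#' the multi-class chance agreement `Pe = sum_k row_k * col_k / N^2` (in the
#' binary case `[(TP+FN)(TP+FP) + (FN+TN)(FP+TN)] / N^2`). Computed in the
#' single-division form `(N*trace - S) / (N^2 - S)` with
#' `S = sum_k row_k col_k`. If both marginals are degenerate on one class
#' (`Pe = 1`), kappa is defined as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  m <- cm_counts(cm)
  n <- sum(m)
  s <- sum(rowSums(m) * colSums(m))
  if (n * n == s) return(0)
  (n * sum(diag(m)) - s) / (n * n - s)
}

#' Qualitative kappa band
#'
#' Maps a kappa value to its consistency label. Bands are upper-inclusive
#' (`0 < kappa <= 0.2` is "Notably low consistency", ..., `0.8 < kappa <= 1`
#' is "Almost complete consistency"); the exact values -1, 0 and +1 carry
#' their own labels, which take precedence. A kappa strictly between -1 and 0
#' indicates below-chance agreement; the qualitative scale does not subdivide
#' that range, so it is labelled "Worse than random".
#'
#' @param k Numeric in `[-1, 1]`.
#' @return Character label.
#' @export
kappa_band <- function(k) {
  if (!is.finite(k) || k < -1 || k > 1) stop("kappa must lie in [-1, 1]")
  if (k == 1) return("Complete consistency")
  if (k == -1) return("Completely inconsistent")
  if (k == 0) return("Random classification results")
  if (k < 0) return("Worse than random")
  if (k <= 0.2) return("Notably low consistency")
  if (k <= 0.4) return("Low consistency")
  if (k <= 0.6) return("Medium consistency")
  if (k <= 0.8) return("High consistency")
  "Almost complete consistency"
}

#' Overall accuracy
#'
#' Sum of correctly classified pixels divided by the total pixel count
#' (trace / N).
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  m <- cm_counts(cm)
  sum(diag(m)) / sum(m)
}

#' Full metrics report for a mask pair
#'
#' Convenience wrapper building the confusion matrix and computing the full
#' indicator suite (binary task) or overall accuracy + kappa (multi-class).
#'
#' @inheritParams confusion_matrix
#' @return For K = 2, the [binary_metrics()] list; otherwise a list with
#'   `oa`, `kappa`, `kappa_band`, and the `confusion` matrix.
#' @export
metrics_report <- function(truth, pred, K, class_names = NULL) {
  cm <- confusion_matrix(truth, pred, K, class_names)
  if (K == 2L) {
    out <- binary_metrics(cm)
    out$confusion <- cm
    out
  } else {
    k <- cohen_kappa(cm)
    list(oa = overall_accuracy(cm), kappa = k, kappa_band = kappa_band(k),
         confusion = cm)
  }
}
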