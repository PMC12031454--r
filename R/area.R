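# Pixel-based area accounting: class areas from pixel counts and the ground
# sample distance, and agreement of model areas with a manually delineated
# reference.

#' Per-class area report
#'
#' Counts pixels per class and converts them to square metres with the ground
#' sample distance: `area_m2 = pixel_count * (gsd_cm / 100)^2`. Areas are
#' exactly representable as pixel count times squared resolution and are
#' additive over disjoint regions.
#'
#' @param mask A `segmentation_mask` (or integer matrix) of class labels.
#' @param gsd_cm Ground sample distance in cm/pixel (> 0).
#' @param class_names Optional named labels; defaults to the gray values
#'   present.
#' @return A data.frame of class `area_report` with columns `class`,
#'   `pixel_count`, `area_m2`, plus attributes `gsd_cm` and `total_m2`.
#' @export
class_area <- function(mask, gsd_cm = 4.61, class_names = NULL) {
  if (gsd_cm <= 0) stop("gsd_cm must be positive")
  m <- as_mask_values(mask)
  classes <- sort(unique(as.vector(m)))
  px_area <- (gsd_cm / 100)^2
  counts <- vapply(classes, function(k) sum(m == k), numeric(1))
  out <- data.frame(class = classes, pixel_count = counts,
                    area_m2 = counts * px_area)
  if (!is.null(class_names)) out$name <- class_names[classes + 1L]
  attr(out, "gsd_cm") <- gsd_cm
  attr(out, "total_m2") <- sum(out$area_m2)
  class(out) <- c("area_report", "data.frame")
  out
}

#' Species-area accuracy against a manual reference
#'
#' For each class, the relative error `|S_D - S_M| / S_D` of the model area
#' `S_M` against the manually delineated reference `S_D`; the mean over
#' classes is the mean relative error, and the reported accuracy is
#' `100 * (1 - mean_error)` percent. The measure is scale-invariant:
#' multiplying all areas by one constant leaves it unchanged. Classes with a
#' zero reference area are excluded and flagged.
#'
#' @param model_areas Named or positional numeric vector of model areas (m2).
#' @param reference_areas Numeric vector of reference areas over the same
#'   class set.
#' @return List with `per_class_relative_error`, `mean_error`,
#'   `accuracy_percent`, and `excluded` (indices/names of zero-reference
#'   classes).
#' @export
species_area_accuracy <- function(model_areas, reference_areas) {
  if (length(model_areas) != length(reference_areas)) {
    stop("model and reference area vectors differ in length")
  }
  keep <- reference_areas > 0
  excluded <- which(!keep)
  if (!any(keep)) stop("no class has a positive reference area")
  err <- abs(reference_areas[keep] - model_areas[keep]) / reference_areas[keep]
  if (!is.null(names(model_areas))) names(err) <- names(model_areas)[keep]
  mean_err <- mean(err)
  list(per_class_relative_error = err,
       mean_error = mean_err,
       accuracy_percent = 100 * (1 - mean_err),
       excluded = excluded)
}
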