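# Seeded synthetic 5-band scenes with ground-truth masks.
#
# The generator emulates the qualitative structure of high-resolution coastal
# UAV imagery: spatially contiguous canopy patches with class-distinct band
# signatures (a dark-green high-NIR canopy, a lighter green one, a light
# conspicuous-edge canopy, and spectrally flat low-NIR water/ground), plus
# optional multiplicative shadow contamination. It makes every other module
# testable end to end; it does not model canopy texture or radiative
# transfer.

#' Default 4-class species signature set
#'
#' Gray values follow the species convention 0..3. Band means (B, G, R, RE,
#' NIR on the 8-bit scale) encode the qualitative contrasts seen in such
#' imagery: Rhizophora stylosa darkest green with the highest NIR, the
#' Aegiceras-Avicennia association a slightly lighter green, Sonneratia
#' apetala the lightest green, and "other" (water, bare ground, structures)
#' spectrally flat with low NIR.
#'
#' @return List of per-class lists with `name`, `gray_value`, `band_means`,
#'   `band_sd`, `vegetation`.
#' @export
default_species_classes <- function() {
  list(
    list(name = "Aegiceras-Avicennia", gray_value = 0L,
         band_means = c(60, 110, 70, 130, 170), band_sd = 8, vegetation = TRUE),
    list(name = "Rhizophora stylosa", gray_value = 1L,
         band_means = c(40, 80, 50, 120, 185), band_sd = 8, vegetation = TRUE),
    list(name = "Sonneratia apetala", gray_value = 2L,
         band_means = c(80, 150, 100, 160, 160), band_sd = 8, vegetation = TRUE),
    list(name = "other", gray_value = 3L,
         band_means = c(90, 95, 90, 80, 40), band_sd = 8, vegetation = FALSE)
  )
}

#' Synthetic scene specification
#'
#' @param height,width Scene dims in pixels.
#' @param classes Class list as in [default_species_classes()]; gray values
#'   must be unique, band means within the 8-bit range, sd >= 0.
#' @param blob_count Gaussian bumps per class controlling region count.
#' @param blob_scale Bump radius as a fraction of the scene's short side.
#' @param shadow_fraction Fraction of vegetated pixels darkened
#'   multiplicatively, in `[0, 1)`.
#' @param seed Integer seed; the scene is fully determined by it.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(height = 128L, width = 128L,
                       classes = default_species_classes(),
                       blob_count = 6L, blob_scale = 0.25,
                       shadow_fraction = 0, seed = 1L) {
  gv <- vapply(classes, function(x) x$gray_value, integer(1))
  if (anyDuplicated(gv)) stop("class gray values must be unique")
  for (cl in classes) {
    if (length(cl$band_means) != 5L || any(cl$band_means < 0) ||
        any(cl$band_means > 255)) {
      stop("band means must be 5 values within the 8-bit range")
    }
    if (cl$band_sd < 0) stop("band_sd must be >= 0")
  }
  if (shadow_fraction < 0 || shadow_fraction >= 1) {
    stop("shadow_fraction must lie in [0, 1)")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 classes = classes, blob_count = as.integer(blob_count),
                 blob_scale = blob_scale, shadow_fraction = shadow_fraction,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# smooth random score field: sum of Gaussian bumps with random centers,
# radii, and amplitudes
blob_field <- function(h, w, blob_count, blob_scale) {
  f <- matrix(0, h, w)
  rr <- matrix(rep(seq_len(h), w), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  s0 <- blob_scale * min(h, w)
  for (j in seq_len(blob_count)) {
    cy <- stats::runif(1, 1, h)
    cx <- stats::runif(1, 1, w)
    s <- s0 * stats::runif(1, 0.5, 1.2)
    a <- stats::runif(1, 0.8, 1.2)
    f <- f + a * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * s^2))
  }
  f
}

#' Generate a synthetic scene
#'
#' Builds the class mask from smoothed random blob fields (per-pixel argmax
#' over per-class score fields, so regions are spatially contiguous), then
#' draws the raster as per-class band means plus Gaussian noise, rounded and
#' clipped to the 8-bit range. If `shadow_fraction > 0`, that fraction of
#' vegetated pixels (chosen as contiguous shadow blobs) is darkened by a
#' single multiplicative factor of 0.45 across all five bands, emulating
#' canopy shadows whose gray values approach the dark classes. The output is
#' fully determined by the spec's seed.
#'
#' @param spec A [scene_spec()].
#' @return List with `raster` (a `multispectral_raster`, 8-bit, GSD 4.61) and
#'   `mask` (a `segmentation_mask` of gray values).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  h <- spec$height
  w <- spec$width
  K <- length(spec$classes)
  scores <- array(0, dim = c(h, w, K))
  for (k in seq_len(K)) {
    scores[, , k] <- blob_field(h, w, spec$blob_count, spec$blob_scale)
  }
  lab_idx <- max.col(matrix(scores, ncol = K), ties.method = "first")
  gv <- vapply(spec$classes, function(x) x$gray_value, integer(1))
  mask <- matrix(gv[lab_idx], h, w)
  values <- array(0, dim = c(h, w, 5L))
  for (k in seq_len(K)) {
    sel <- lab_idx == k
    n <- sum(sel)
    if (n == 0L) next
    cl <- spec$classes[[k]]
    for (b in 1:5) {
      v <- cl$band_means[b]
      if (cl$band_sd > 0) v <- v + stats::rnorm(n, 0, cl$band_sd)
      slab <- values[, , b]
      slab[sel] <- v
      values[, , b] <- slab
    }
  }
  if (spec$shadow_fraction > 0) {
    veg <- matrix(vapply(spec$classes, function(x) isTRUE(x$vegetation),
                         logical(1))[lab_idx], h, w)
    sf <- blob_field(h, w, max(3L, spec$blob_count), spec$blob_scale / 2)
    vals <- sf[veg]
    thr <- stats::quantile(vals, 1 - spec$shadow_fraction, names = FALSE)
    shade <- veg & (sf > thr)
    for (b in 1:5) {
      slab <- values[, , b]
      slab[shade] <- slab[shade] * 0.45
      values[, , b] <- slab
    }
  }
  values <- pmin(pmax(round_half_up(values), 0), 255)
  list(raster = multispectral_raster(values, gsd_cm = 4.61),
       mask = segmentation_mask(mask))
}

#' Binary extent mask from a species mask
#'
#' Maps the vegetated (mangrove) gray values to 1 and everything else to 0.
#'
#' @param mask A `segmentation_mask` of gray values.
#' @param vegetation Gray values counting as mangrove (default 0, 1, 2).
#' @return A binary `segmentation_mask`.
#' @export
extent_mask <- function(mask, vegetation = c(0L, 1L, 2L)) {
  m <- as_mask_values(mask)
  segmentation_mask(matrix(as.integer(m %in% vegetation), nrow(m), ncol(m)))
}

#' Generate a paired tile/label set
#'
#' Draws scenes (each four tile-sides square, seeded `spec$seed`,
#' `spec$seed + 1000`, ...) and cuts them with [make_tile_grid()] so tiles
#' and labels share anchors by construction, until `n_tiles` pairs exist.
#'
#' @param spec A [scene_spec()]; its height/width are overridden by the scene
#'   side used here.
#' @param n_tiles Number of tile pairs wanted (>= 1).
#' @param tile_size Tile side in pixels.
#' @param overlap Grid overlap in pixels (default 0).
#' @return List with `tiles` (list of (ts, ts, 5) arrays), `masks` (list of
#'   `segmentation_mask`s), and `class_balance` (named fraction table over
#'   gray values).
#' @export
generate_tileset <- function(spec, n_tiles, tile_size, overlap = 0L) {
  if (n_tiles < 1L) stop("n_tiles must be >= 1")
  side <- 4L * as.integer(tile_size)
  tiles <- list()
  masks <- list()
  i <- 0L
  while (length(tiles) < n_tiles) {
    sp <- spec
    sp$height <- side
    sp$width <- side
    sp$seed <- spec$seed + 1000L * i
    sc <- generate_scene(sp)
    grid <- make_tile_grid(side, side, tile_size, overlap)
    tiles <- c(tiles, extract_tiles(sc$raster, grid))
    masks <- c(masks, lapply(extract_tiles(sc$mask, grid), segmentation_mask))
    i <- i + 1L
  }
  tiles <- tiles[seq_len(n_tiles)]
  masks <- masks[seq_len(n_tiles)]
  all_lab <- unlist(lapply(masks, as.vector))
  list(tiles = tiles, masks = masks,
       class_balance = table(all_lab) / length(all_lab))
}
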