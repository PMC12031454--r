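#' Multispectral raster container
#'
#' An in-memory H x W x C raster with band metadata. The default band order
#' follows the Phantom 4RTK multispectral sensor: Blue, Green, Red, RedEdge,
#' NIR. Values must lie within the bit-depth range.
#'
#' @param values Numeric array (H, W, C).
#' @param band_names Character vector of length C.
#' @param bit_depth 8 or 16.
#' @param gsd_cm Ground sample distance in cm/pixel (4.61 for the source
#'   sensor in ortho mode).
#' @param geo_tag Optional list of projection/transform metadata, passed
#'   through I/O untouched.
#' @return Object of class `multispectral_raster`.
#' @export
multispectral_raster <- function(values,
                                 band_names = c("B", "G", "R", "RE", "NIR"),
                                 bit_depth = 8L, gsd_cm = 4.61,
                                 geo_tag = NULL) {
  d <- dims3(values)
  if (d[3L] != length(band_names)) {
    stop("got ", d[3L], " bands but ", length(band_names), " band names")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (gsd_cm <= 0) stop("gsd_cm must be positive")
  vmax <- 2^bit_depth - 1
  if (min(values) < 0 || max(values) > vmax) {
    stop("values outside the ", bit_depth, "-bit range [0, ", vmax, "]")
  }
  structure(list(values = values, band_names = band_names,
                 bit_depth = as.integer(bit_depth), gsd_cm = gsd_cm,
                 geo_tag = geo_tag),
            class = "multispectral_raster")
}

#' Segmentation mask container
#'
#' An integer H x W class raster sharing geometry with its source raster:
#' \{0, 1\} for the extent task, \{0, 1, 2, 3\} (the species gray-value
#' convention) for the species task.
#'
#' @param m Integer matrix of non-negative labels.
#' @return Object of class `segmentation_mask` (an integer matrix).
#' @export
segmentation_mask <- function(m) {
  if (!is.matrix(m)) stop("mask must be a matrix")
  storage.mode(m) <- "integer"
  if (any(m < 0L)) stop("mask labels must be non-negative")
  structure(m, class = "segmentation_mask")
}

as_mask_values <- function(x) {
  if (inherits(x, "segmentation_mask")) unclass(x) else {
    m <- x
    storage.mode(m) <- "integer"
    m
  }
}

raster_values <- function(x) {
  if (inherits(x, "multispectral_raster")) x$values else x
}

# round half away from zero (values here are non-negative)
round_half_up <- function(x) floor(x + 0.5)

#' Convert a 16-bit raster to 8-bit
#'
#' Linearly rescales each band's `[min, max]` onto `[0, 255]`, rounding half
#' away from zero. A constant band maps to 0. An already-8-bit raster is
#' returned unchanged with a warning.
#'
#' @param r A `multispectral_raster` with `bit_depth = 16`.
#' @return A `multispectral_raster` with `bit_depth = 8`. The conversion is
#'   monotone non-decreasing per band.
#' @export
convert_16_to_8bit <- function(r) {
  stopifnot(inherits(r, "multispectral_raster"))
  if (r$bit_depth == 8L) {
    warning("raster is already 8-bit; returning it unchanged")
    return(r)
  }
  v <- r$values
  for (c in seq_len(dim(v)[3L])) {
    b <- v[, , c]
    rng <- range(b)
    v[, , c] <- if (rng[1L] == rng[2L]) 0 else
      round_half_up((b - rng[1L]) * 255 / (rng[2L] - rng[1L]))
  }
  multispectral_raster(v, r$band_names, bit_depth = 8L, gsd_cm = r$gsd_cm,
                       geo_tag = r$geo_tag)
}

#' Deterministic tile grid
#'
#' Produces the ordered (row-major) list of fixed-size windows covering an
#' H x W raster. Interior anchors advance by `tile_size - overlap` (362 px at
#' the 512/150 defaults); if the last regular anchor does not reach the edge,
#' a final anchor clamped to `dim - tile_size` is appended so every pixel is
#' covered by a fully in-bounds window.
#'
#' @param h,w Raster dims, both at least `tile_size`.
#' @param tile_size Window side (default 512).
#' @param overlap Overlap between neighboring interior windows (default 150).
#' @return Object of class `tile_grid`: list with `tile_size`, `overlap`, and
#'   `windows`, a two-column matrix of 0-based (row0, col0) anchors.
#' @export
make_tile_grid <- function(h, w, tile_size = 512L, overlap = 150L) {
  tile_size <- as.integer(tile_size)
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= tile_size) {
    stop("overlap must lie in [0, tile_size)")
  }
  if (h < tile_size || w < tile_size) {
    stop("raster (", h, "x", w, ") is smaller than the tile size ", tile_size,
         "; pad it before tiling")
  }
  anchors <- function(n) {
    stride <- tile_size - overlap
    a <- seq.int(0L, n - tile_size, by = stride)
    if (a[length(a)] + tile_size < n) a <- c(a, n - tile_size)
    unique(a)
  }
  rows <- anchors(as.integer(h))
  cols <- anchors(as.integer(w))
  windows <- cbind(row0 = rep(rows, each = length(cols)),
                   col0 = rep(cols, times = length(rows)))
  structure(list(tile_size = tile_size, overlap = overlap, windows = windows),
            class = "tile_grid")
}

#' Extract tiles along a grid
#'
#' @param r A `multispectral_raster`, 3-D array, or `segmentation_mask`.
#' @param grid A [make_tile_grid()] grid for the raster's geometry.
#' @return List of tiles (arrays or matrices, matching the input kind), in
#'   the grid's window order.
#' @export
extract_tiles <- function(r, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  ts <- grid$tile_size
  is_mask <- inherits(r, "segmentation_mask") ||
    (is.matrix(r) && !inherits(r, "multispectral_raster"))
  v <- if (is_mask) as_mask_values(r) else raster_values(r)
  apply_window <- function(a) {
    ri <- (a[1L] + 1L):(a[1L] + ts)
    ci <- (a[2L] + 1L):(a[2L] + ts)
    if (is_mask) v[ri, ci, drop = FALSE] else v[ri, ci, , drop = FALSE]
  }
  lapply(seq_len(nrow(grid$windows)), function(i) apply_window(grid$windows[i, ]))
}

#' Mosaic tiles back to scene geometry
#'
#' Reassembles tiles produced by [extract_tiles()] (or predicted maps of the
#' same geometry). Mode `"overwrite"` writes tiles in grid order (overlaps
#' between tiles cut from one raster are identical by construction, so the
#' extract-mosaic round trip is exact). Mode `"average"` averages overlapping
#' values, the appropriate choice for probability maps before
#' thresholding/argmax.
#'
#' @param tiles List of (ts, ts, C) arrays or (ts, ts) matrices, one per grid
#'   window.
#' @param grid The [make_tile_grid()] used to cut them.
#' @param mode `"overwrite"` or `"average"`.
#' @return Array (H, W, C) or matrix (H, W) at the scene geometry.
#' @export
mosaic_tiles <- function(tiles, grid, mode = c("overwrite", "average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "tile_grid"))
  nw <- nrow(grid$windows)
  if (length(tiles) != nw) {
    stop("grid has ", nw, " windows but ", length(tiles), " tiles supplied")
  }
  ts <- grid$tile_size
  h <- max(grid$windows[, 1L]) + ts
  w <- max(grid$windows[, 2L]) + ts
  first <- tiles[[1L]]
  is_mat <- is.matrix(first)
  C <- if (is_mat) 1L else dim(first)[3L]
  acc <- array(0, dim = c(h, w, C))
  cnt <- if (mode == "average") matrix(0L, h, w) else NULL
  for (i in seq_len(nw)) {
    a <- grid$windows[i, ]
    ri <- (a[1L] + 1L):(a[1L] + ts)
    ci <- (a[2L] + 1L):(a[2L] + ts)
    tl <- tiles[[i]]
    if (is_mat) dim(tl) <- c(ts, ts, 1L)
    if (mode == "overwrite") {
      acc[ri, ci, ] <- tl
    } else {
      acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] + tl
      cnt[ri, ci] <- cnt[ri, ci] + 1L
    }
  }
  if (mode == "average") {
    acc <- acc / array(cnt, dim = c(h, w, C))
  }
  if (is_mat) acc[, , 1L] else acc
}

#' Seeded train/validation split
#'
#' Uniformly shuffles the ids with the given seed and assigns the first
#' `round(fraction * N)` to training. At the study's N = 10,560 and fraction
#' 0.8 this yields exactly 8448 training and 2112 validation ids.
#'
#' @param ids Vector of at least 2 ids.
#' @param fraction Training fraction in (0, 1) (default 0.8).
#' @param seed Integer seed.
#' @return Object of class `dataset_split`: list with `train_ids`, `val_ids`,
#'   `fraction`, `seed`.
#' @export
split_dataset <- function(ids, fraction = 0.8, seed = 1L) {
  if (length(ids) < 2L) stop("need at least 2 ids to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perm <- sample(ids)
  ntr <- round(fraction * length(ids))
  val <- if (ntr < length(ids)) perm[(ntr + 1L):length(ids)] else perm[0L]
  structure(list(train_ids = perm[seq_len(ntr)],
                 val_ids = val,
                 fraction = fraction, seed = as.integer(seed)),
            class = "dataset_split")
}

# ---- raster I/O -------------------------------------------------------------

meta_path <- function(path) paste0(path, ".meta.json")

#' Read / write multispectral rasters
#'
#' Rasters are stored as multi-page TIFF (one directory per band, preserving
#' the configured band order) with a JSON sidecar (`<path>.meta.json`)
#' carrying band names, bit depth, ground sample distance, and the geo tag.
#' The write-then-read round trip is lossless for values, band order, and
#' geo tag.
#'
#' @param path TIFF file path.
#' @return `read_raster` returns a `multispectral_raster`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1L]])
  w <- ncol(pages[[1L]])
  for (i in seq_along(pages)) {
    if (nrow(pages[[i]]) != h || ncol(pages[[i]]) != w) {
      stop("band ", i, " of ", path, " has inconsistent geometry")
    }
  }
  v <- array(0, dim = c(h, w, length(pages)))
  for (i in seq_along(pages)) v[, , i] <- pages[[i]]
  meta <- if (file.exists(meta_path(path))) {
    jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
  } else {
    list(band_names = paste0("band", seq_along(pages)), bit_depth = 8L,
         gsd_cm = 4.61, geo_tag = NULL)
  }
  if (length(meta$band_names) != length(pages)) {
    stop("raster ", path, " has ", length(pages), " bands but metadata names ",
         length(meta$band_names), " (", paste(meta$band_names, collapse = ","), ")")
  }
  multispectral_raster(v, meta$band_names, bit_depth = meta$bit_depth,
                       gsd_cm = meta$gsd_cm, geo_tag = meta$geo_tag)
}

#' @rdname read_raster
#' @param r A `multispectral_raster`.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "multispectral_raster"))
  scale <- 2^r$bit_depth - 1
  pages <- lapply(seq_len(dim(r$values)[3L]), function(c) r$values[, , c] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = r$bit_depth)
  jsonlite::write_json(list(band_names = r$band_names, bit_depth = r$bit_depth,
                            gsd_cm = r$gsd_cm, geo_tag = r$geo_tag),
                       meta_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read / write segmentation masks
#'
#' Masks are single-band 8-bit TIFFs holding the class gray values directly
#' (0..3 for the species convention).
#'
#' @param path TIFF file path.
#' @return `read_mask` returns a `segmentation_mask`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (!is.matrix(m)) stop("mask ", path, " is not single-band")
  segmentation_mask(m)
}

#' @rdname read_mask
#' @param mask A `segmentation_mask` (or integer matrix) with values 0..255.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_values(mask)
  if (max(m) > 255L) stop("mask gray values exceed 8-bit range")
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  invisible(path)
}
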