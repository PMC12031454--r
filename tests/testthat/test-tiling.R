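test_that("tile grids reproduce the worked anchor patterns", {
  g1 <- make_tile_grid(512, 512)
  expect_equal(nrow(g1$windows), 1L)
  expect_equal(unname(g1$windows[1, ]), c(0L, 0L))
  # 874 = 362 + 512 exactly: two windows per axis direction
  g2 <- make_tile_grid(874, 512)
  expect_equal(unique(g2$windows[, 1]), c(0L, 362L))
  # 1000: last anchor clamped to 1000 - 512 = 488
  g3 <- make_tile_grid(1000, 512)
  expect_equal(unique(g3$windows[, 1]), c(0L, 362L, 488L))
  expect_error(make_tile_grid(400, 600), "pad")
})

test_that("every pixel is covered by an in-bounds window", {
  set.seed(31)
  for (rep in 1:20) {
    h <- sample(40:140, 1)
    w <- sample(40:140, 1)
    ts <- sample(20:40, 1)
    ov <- sample(0:(ts - 1), 1)
    g <- make_tile_grid(h, w, ts, ov)
    expect_true(all(g$windows[, 1] >= 0 & g$windows[, 1] + ts <= h))
    expect_true(all(g$windows[, 2] >= 0 & g$windows[, 2] + ts <= w))
    cov <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(g$windows))) {
      a <- g$windows[i, ]
      cov[(a[1] + 1):(a[1] + ts), (a[2] + 1):(a[2] + ts)] <- TRUE
    }
    expect_true(all(cov))
  }
})

test_that("extract then mosaic is the identity for imagery", {
  set.seed(32)
  for (rep in 1:10) {
    h <- sample(50:120, 1)
    w <- sample(50:120, 1)
    v <- array(as.numeric(sample(0:255, h * w * 5, replace = TRUE)), c(h, w, 5))
    r <- multispectral_raster(v)
    g <- make_tile_grid(h, w, 32, 9)
    back <- mosaic_tiles(extract_tiles(r, g), g, "overwrite")
    expect_identical(back, v)
  }
})

test_that("average mosaicking means overlapping probability tiles", {
  g <- make_tile_grid(32, 54, 32, 10)   # two windows overlapping in columns
  expect_equal(nrow(g$windows), 2L)
  t1 <- array(0.2, c(32, 32, 1))
  t2 <- array(0.6, c(32, 32, 1))
  mo <- mosaic_tiles(list(t1, t2), g, "average")
  overlap_cols <- 23:32   # second window starts at col0 = 22
  expect_true(all(mo[, overlap_cols, 1] == 0.4))
  expect_true(all(mo[, 1:22, 1] == 0.2))
  expect_true(all(mo[, 33:54, 1] == 0.6))
  expect_error(mosaic_tiles(list(t1), g, "average"), "windows")
})

test_that("16-to-8-bit conversion follows the linear rescale with half-up rounding", {
  v <- array(0, c(1, 3, 1))
  v[1, , 1] <- c(0, 256, 65535)
  r <- multispectral_raster(v, band_names = "NIR", bit_depth = 16L)
  r8 <- convert_16_to_8bit(r)
  expect_equal(as.vector(r8$values), c(0, 1, 255))
  expect_equal(r8$bit_depth, 8L)
  # endpoints and constant bands
  v2 <- array(c(0, 65535, 12000, 12000), c(2, 1, 2))
  r2 <- convert_16_to_8bit(multispectral_raster(v2, band_names = c("a", "b"),
                                                bit_depth = 16L))
  expect_equal(as.vector(r2$values[, , 1]), c(0, 255))
  expect_true(all(r2$values[, , 2] == 0))
  expect_warning(convert_16_to_8bit(r2), "already 8-bit")
  # monotone non-decreasing per band
  set.seed(33)
  v3 <- array(sample(0:65535, 64, replace = TRUE), c(8, 8, 1))
  r3 <- convert_16_to_8bit(multispectral_raster(v3, band_names = "x", bit_depth = 16L))
  o <- order(v3)
  expect_true(all(diff(as.vector(r3$values)[o]) >= 0))
})

test_that("the 80/20 split has the printed cardinalities and is a seeded partition", {
  s <- split_dataset(seq_len(10560), 0.8, seed = 9)
  expect_length(s$train_ids, 8448L)
  expect_length(s$val_ids, 2112L)
  expect_setequal(c(s$train_ids, s$val_ids), seq_len(10560))
  expect_length(intersect(s$train_ids, s$val_ids), 0L)
  s2 <- split_dataset(seq_len(10560), 0.8, seed = 9)
  expect_identical(s, s2)
  s3 <- split_dataset(1:10, 0.8, seed = 1)
  expect_length(s3$train_ids, 8L)
  expect_error(split_dataset(1:10, 1.2), "fraction")
})

test_that("raster and mask I/O round-trips values, band order, and geo tag", {
  set.seed(34)
  v <- array(as.numeric(sample(0:255, 20 * 15 * 5, replace = TRUE)), c(20, 15, 5))
  geo <- list(crs = "WGS_1984_UTM_Zone_49N",
              transform = c(500000.5, 0.0461, 0, 2330000.25, 0, -0.0461))
  r <- multispectral_raster(v, gsd_cm = 4.61, geo_tag = geo)
  path <- file.path(tempdir(), "scene.tif")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_identical(r2$values, v)
  expect_identical(r2$band_names, c("B", "G", "R", "RE", "NIR"))
  expect_equal(r2$geo_tag$crs, geo$crs)
  expect_equal(r2$geo_tag$transform, geo$transform)
  expect_equal(r2$gsd_cm, 4.61)
  # masks hold the species gray values directly
  m <- segmentation_mask(matrix(sample(0:3, 48, replace = TRUE), 8, 6))
  mpath <- file.path(tempdir(), "mask.tif")
  write_mask(m, mpath)
  expect_identical(unclass(read_mask(mpath)), unclass(m))
  expect_error(read_raster(file.path(tempdir(), "no_such.tif")), "not found")
  unlink(c(path, meta_path <- paste0(path, ".meta.json"), mpath))
})
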