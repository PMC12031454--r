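test_that("model builds are deterministic in the seed", {
  cfg <- mangrovenet_config(5, c(8, 16, 32), seed = 7)
  m1 <- build_mangrovenet(cfg)
  m2 <- build_mangrovenet(cfg)
  expect_identical(m1$store$params, m2$store$params)
  n_par <- sum(vapply(m1$store$params, length, numeric(1)))
  expect_identical(n_par,
                   sum(vapply(build_mangrovenet(cfg)$store$params, length, numeric(1))))
  m3 <- build_mangrovenet(mangrovenet_config(5, c(8, 16, 32), seed = 8))
  expect_false(identical(m1$store$params, m3$store$params))
})

test_that("a zero tile yields probability 0.5 everywhere and shapes are kept", {
  m <- build_mangrovenet(mangrovenet_config(5, c(4, 8, 8), seed = 1))
  p <- predict_prob(m, array(0, c(64, 64, 5)))
  expect_equal(dim(p), c(64L, 64L, 1L))
  expect_true(all(p == 0.5))
  # full-size tile forward keeps geometry; output strictly inside (0, 1)
  set.seed(61)
  big <- array(sample(0:255, 512 * 512 * 5, replace = TRUE), c(512, 512, 5))
  m2 <- build_mangrovenet(mangrovenet_config(5, c(2, 3, 4), seed = 1))
  pb <- predict_prob(m2, big)
  expect_equal(dim(pb), c(512L, 512L, 1L))
  expect_true(all(pb > 0 & pb < 1))
  expect_error(predict_prob(m, array(0, c(30, 30, 5))), "divisible by 4")
  expect_error(predict_prob(m, array(0, c(64, 64, 3))), "bands")
})

test_that("multi-scale fusion matches its closed forms and loop oracle", {
  base <- array(2, c(8, 8, 3))
  zero <- array(0, c(8, 8, 3))
  expect_equal(fuse_multiscale(list(zero), base), base)
  # constants: nearest-neighbour upsampling keeps them constant
  c1 <- array(1.5, c(4, 4, 3))
  c2 <- array(-0.5, c(2, 2, 3))
  expect_true(all(fuse_multiscale(list(c1, c2), base) == 2 + 1.5 - 0.5))
  # random 3-scale case against an explicit loop
  set.seed(62)
  b <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  s1 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  s2 <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  s3 <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  got <- fuse_multiscale(list(s1, s2, s3), b)
  want <- array(0, c(8, 8, 2))
  for (i in 1:8) for (j in 1:8) for (c in 1:2) {
    want[i, j, c] <- b[i, j, c] + s1[i, j, c] +
      s2[ceiling(i / 2), ceiling(j / 2), c] + s3[ceiling(i / 4), ceiling(j / 4), c]
  }
  expect_equal(got, want, tolerance = 1e-6)
  expect_error(fuse_multiscale(list(array(0, c(3, 3, 2))), b), "mismatch")
})

test_that("the segmentation head applies sigmoid to summed 1-channel projections", {
  par <- list(w_fused = array(0, c(1, 1, 3, 1)), b_fused = 0,
              w_up = array(0, c(1, 1, 2, 1)), b_up = 0)
  fused <- array(rnorm(16 * 3), c(4, 4, 3))
  up <- array(rnorm(16 * 2), c(4, 4, 2))
  expect_true(all(segmentation_head(fused, up, par) == 0.5))
  # a pixel whose projected sum is ln(3) maps to 0.75
  par2 <- par
  par2$b_fused <- log(3)
  expect_equal(as.vector(segmentation_head(fused, up, par2)),
               rep(0.75, 16))
  # random projections against a scalar-loop sigmoid
  set.seed(63)
  par3 <- list(w_fused = array(rnorm(3), c(1, 1, 3, 1)), b_fused = 0.2,
               w_up = array(rnorm(2), c(1, 1, 2, 1)), b_up = -0.1)
  got <- segmentation_head(fused, up, par3)
  for (i in 1:4) for (j in 1:4) {
    z <- sum(fused[i, j, ] * par3$w_fused[1, 1, , 1]) + par3$b_fused +
      sum(up[i, j, ] * par3$w_up[1, 1, , 1]) + par3$b_up
    expect_equal(got[i, j, 1], 1 / (1 + exp(-z)), tolerance = 1e-7)
  }
})

test_that("binary cross-entropy hits its closed forms", {
  t <- c(1, 1, 0, 0)
  expect_lt(bce_loss(t, t), 1e-6)
  expect_equal(bce_loss(rep(0.5, 4), t), log(2))
  p <- c(0.9, 0.8, 0.3, 0.4)
  expect_equal(bce_loss(p, t), mean(-log(c(0.9, 0.8, 0.7, 0.6))))
  expect_equal(round(bce_loss(p, t), 4), 0.299)
  expect_error(bce_loss(p, c(1, 2, 0, 0)), "0 or 1")
})

test_that("index unpooling is a right inverse of max-pooling", {
  ns <- asNamespace("mangroveseg")
  set.seed(64)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  tape <- ns$ag_tape()
  xn <- ns$ag_node(tape, x)
  p <- ns$ag_maxpool2(xn, tape)
  u <- ns$ag_unpool2(p, p, tape)
  # maxima restored in place, zeros elsewhere
  expect_equal(sum(u$value != 0), length(p$value))
  for (c in 1:3) for (i in 1:4) for (j in 1:4) {
    blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]
    ublk <- u$value[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]
    at <- which.max(blk)
    expect_equal(ublk[at], blk[at])
    expect_true(all(ublk[-at] == 0))
  }
})

test_that("thresholding follows the >= convention and is monotone", {
  m <- build_mangrovenet(mangrovenet_config(5, c(4, 8, 8), seed = 1))
  tile <- array(0, c(16, 16, 5))
  # probability exactly 0.5 everywhere -> all ones at threshold 0.5
  expect_true(all(unclass(predict_mask(m, tile, 0.5)) == 1L))
  # threshold 1.0 on outputs strictly below 1 -> all zeros
  expect_true(all(unclass(predict_mask(m, tile, 1.0)) == 0L))
  set.seed(65)
  tile2 <- array(sample(0:255, 16 * 16 * 5, replace = TRUE), c(16, 16, 5))
  m1 <- unclass(predict_mask(m, tile2, 0.3))
  m2 <- unclass(predict_mask(m, tile2, 0.7))
  expect_true(all(m2 <= m1))
})

test_that("training descends on a separable tile and is seed-reproducible", {
  set.seed(66)
  tile <- array(30, c(16, 16, 5))
  tile[1:8, , 5] <- 200   # strong NIR contrast marks the positive half
  mask <- segmentation_mask(rbind(matrix(1L, 8, 16), matrix(0L, 8, 16)))
  m <- build_mangrovenet(mangrovenet_config(5, c(4, 8, 8), seed = 2))
  tc <- train_config(max_iterations = 200, batch_size = 1, seed = 3)
  fit <- train_model(m, list(tile), list(mask), tc)
  expect_lt(fit$history[200], fit$history[1])
  m2 <- build_mangrovenet(mangrovenet_config(5, c(4, 8, 8), seed = 2))
  fit2 <- train_model(m2, list(tile), list(mask), tc)
  expect_identical(fit$history, fit2$history)
  expect_error(train_model(m, list(), list(), tc), "empty")
})
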