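# Hand-crafted contralateral / local / global features and the F4 network.

test_that("cell statistics match direct enumeration on the 4x4 toy slice", {
  sl <- matrix(1:16, 4, 4, byrow = TRUE)
  msk <- matrix(1L, 4, 4)
  g <- cell_statistics(sl, msk, cell_size = 2)
  # top-left cell holds {1, 2, 5, 6}
  expect_equal(g$max[1, 1], 6)
  expect_equal(g$mean[1, 1], 3.5)
  expect_equal(g$median[1, 1], 3.5)
  expect_equal(g$occupancy[1, 1], 4L)

  cst <- cell_statistics(matrix(40, 8, 8), matrix(1L, 8, 8), 4)
  expect_true(all(cst$max == 40 & cst$mean == 40 & cst$median == 40))

  empty <- cell_statistics(sl, matrix(0L, 4, 4), 2)
  expect_true(all(is.na(empty$max)))
  expect_true(all(empty$occupancy == 0))
  expect_error(cell_statistics(sl, msk, cell_size = 10),
               class = "strokeloc_parameter_error")
})

test_that("contralateral pairing mirrors cell columns across the midline", {
  sl <- matrix(0, 128, 128)
  msk <- matrix(1L, 128, 128)
  g <- cell_statistics(sl, msk, 16)      # 8 cell columns
  mid <- 63.5                            # exact image centre
  expect_equal(contralateral_pair(1, g, mid), 8L)
  expect_equal(contralateral_pair(2, g, mid), 7L)
  expect_equal(contralateral_pair(8, g, mid), 1L)
  # a cell centred on the midline pairs with itself (odd cell count)
  g3 <- cell_statistics(matrix(0, 48, 48), matrix(1L, 48, 48), 16)
  expect_equal(contralateral_pair(2, g3, 23.5), 2L)
  # off-centre midline pushes the mirror off the grid -> NA
  expect_true(is.na(contralateral_pair(1, g, 120)))
})

test_that("global features reduce to the in-mask max/mean/median", {
  sl <- matrix(-1000, 4, 4)
  sl[1, 1:4] <- c(10, 20, 30, 100)
  msk <- matrix(0L, 4, 4); msk[1, ] <- 1L
  g <- global_features(sl, msk)
  expect_equal(unname(g), c(100, 40, 25))
  # out-of-mask pixels change nothing
  sl2 <- sl; sl2[3, 3] <- 9999 - 7000
  expect_equal(global_features(sl2, msk), g)
  expect_error(global_features(sl, matrix(0L, 4, 4)),
               class = "strokeloc_parameter_error")
})

test_that("local window statistics behave on constant and impulse slices", {
  cfg <- feature_config(scales = c(8, 16))
  con <- matrix(40, 24, 24)
  msk <- matrix(1L, 24, 24)
  lw <- local_window_features(con, msk, cfg)
  expect_true(all(lw$scales[["8"]]$max == 40))
  expect_true(all(lw$scales[["8"]]$mean == 40))
  expect_true(all(abs(lw$bilat - 40) < 1e-9))  # bilateral preserves constants

  imp <- matrix(40, 33, 33); imp[17, 17] <- 100
  li <- local_window_features(imp, matrix(1L, 33, 33), cfg)
  expect_equal(li$scales[["8"]]$max[17, 17], 100)
  # symmetric nominal-8 window holds 9x9 = 81 pixels
  expect_equal(li$scales[["8"]]$mean[17, 17], 40 + 60 / 81)
  expect_equal(li$scales[["8"]]$median[17, 17], 40)

  # a window covering the whole slice reproduces the global statistics
  sl <- matrix(rnorm(16 * 16, 35, 5), 16, 16)
  mk <- matrix(as.integer(runif(256) > 0.3), 16, 16)
  g <- global_features(sl, mk)
  lg <- local_window_features(sl, mk, feature_config(scales = 32))
  expect_equal(max(abs(lg$scales[["32"]]$max - g[["max"]])), 0)
  expect_lt(max(abs(lg$scales[["32"]]$mean - g[["mean"]])), 1e-9)
  expect_equal(max(abs(lg$scales[["32"]]$median - g[["median"]])), 0)
})

test_that("window and cell statistics match brute-force oracles", {
  set.seed(77)
  for (rep in 1:3) {
    sl <- matrix(rnorm(64 * 64, 35, 8), 64, 64)
    mk <- matrix(as.integer(runif(64 * 64) > 0.25), 64, 64)
    for (w in c(8, 16)) {
      got <- strokeloc:::cpp_window_stats(sl, mk, w %/% 2)
      ora <- oracle_window_stats(sl, mk, w)
      expect_identical(is.na(got$max), is.na(ora$max))
      ok <- !is.na(ora$max)
      expect_equal(got$max[ok], ora$max[ok], tolerance = 0)
      expect_equal(got$median[ok], ora$median[ok], tolerance = 0)
      expect_lt(max(abs(got$mean[ok] - ora$mean[ok])), 1e-9)
    }
    cg <- cell_statistics(sl, mk, 16)
    oc <- oracle_cell_stats(sl, mk, 16)
    ok <- !is.na(oc$max)
    expect_equal(cg$max[ok], oc$max[ok], tolerance = 0)
    expect_equal(cg$median[ok], oc$median[ok], tolerance = 0)
    expect_lt(max(abs(cg$mean[ok] - oc$mean[ok])), 1e-9)
  }
})

test_that("the assembled pixel vector has the documented length and order", {
  p <- tiny_case(seed = 8L)
  sl <- p$ct$slices[, , 2]
  msk <- extract_brain_mask(sl)
  one <- assemble_pixel_features(sl, msk, feature_config(scales = 16))
  expect_equal(dim(one)[3], 13)
  three <- assemble_pixel_features(sl, msk, feature_config())
  expect_equal(dim(three)[3], 21)
  expect_equal(dimnames(three)[[3]][7], "K8_max")
  expect_equal(dimnames(three)[[3]][19:21],
               c("G_max", "G_mean", "G_median"))
  expect_true(all(is.finite(three)))

  # mirror-symmetric slice: own-cell and contralateral features coincide
  half <- matrix(rnorm(32 * 16, 35, 5), 32, 16)
  sym <- cbind(half, half[, 16:1])
  mk <- matrix(1L, 32, 32)
  f <- assemble_pixel_features(sym, mk, feature_config(cell_size = 8,
                                                       scales = 8))
  expect_equal(unname(f[, , 1:3]), unname(f[, , 4:6]), tolerance = 1e-12)
})

test_that("mirroring the slice mirrors C and K maps and fixes G", {
  p <- tiny_case(seed = 9L)
  sl <- p$ct$slices[, , 2]
  msk <- unclass(extract_brain_mask(sl))
  cfg <- feature_config(cell_size = 8, scales = c(8, 16))
  f <- assemble_pixel_features(sl, msk, cfg)
  W <- ncol(sl)
  fm <- assemble_pixel_features(sl[, W:1], msk[, W:1], cfg)
  for (ch in seq_len(dim(f)[3])) {
    # equality up to floating-point summation order (means, bilateral)
    expect_equal(fm[, W:1, ch], f[, , ch], tolerance = 1e-12,
                 label = dimnames(f)[[3]][ch])
  }
})

test_that("the pixel net separates separable classes and is seeded", {
  set.seed(123)
  n <- 500
  X1 <- cbind(rnorm(n, -2), rnorm(n, 0))
  X2 <- cbind(rnorm(n, 2), rnorm(n, 0))
  X <- rbind(X1, X2); y <- rep(1:2, each = n)
  set.seed(55)
  fit <- strokeloc:::mlp_train(X, y, hidden = c(16, 8), epochs = 30,
                               batch = 128)
  ho <- rbind(cbind(rnorm(200, -2), rnorm(200, 0)),
              cbind(rnorm(200, 2), rnorm(200, 0)))
  hy <- rep(1:2, each = 200)
  acc <- mean(max.col(strokeloc:::mlp_predict(fit$layers, ho)) == hy)
  glm_fit <- glm(I(y == 2) ~ X[, 1] + X[, 2], family = binomial)
  acc_glm <- mean((predict(glm_fit,
                           newdata = data.frame(X = I(ho))) > 0) == (hy == 2))
  expect_gte(acc, 0.95)
  expect_gte(acc_glm, 0.95)   # the oracle agrees the task is separable

  set.seed(55)
  fit2 <- strokeloc:::mlp_train(X, y, hidden = c(16, 8), epochs = 30,
                                batch = 128)
  expect_identical(fit$train_loss, fit2$train_loss)
  expect_identical(fit$layers, fit2$layers)

  # untrained network: uniform class probabilities
  set.seed(1)
  net0 <- strokeloc:::mlp_init(5, c(8), 2)
  p0 <- strokeloc:::mlp_predict(net0, matrix(rnorm(50), 10, 5))
  expect_true(all(abs(p0 - 0.5) < 1e-12))
})

test_that("F4 prediction is a masked probability map", {
  p <- tiny_case(seed = 10L)
  cfg <- feature_config(cell_size = 8, scales = c(8, 16))
  msk <- extract_brain_mask_volume(p$ct)
  fm <- lapply(1:3, function(k)
    assemble_pixel_features(p$ct$slices[, , k], msk[, , k], cfg))
  lb <- lapply(1:3, function(k) (p$truth[, , k] > 0) * 2L)
  mks <- lapply(1:3, function(k) msk[, , k])
  model <- train_pixel_net(fm, lb, mks, config = cfg, epochs = 10, seed = 3L)
  f4 <- predict_f4(model, p$ct$slices[, , 2], msk[, , 2],
                   features = fm[[2]])
  expect_true(all(f4 >= 0 & f4 <= 1))
  expect_true(all(f4[msk[, , 2] == 0] == 0))
  # all-out-of-mask slice -> all-zero map
  f0 <- predict_f4(model, p$ct$slices[, , 2] * 0 - 1000,
                   matrix(0L, 48, 48),
                   features = fm[[2]] * 0)
  expect_true(all(f0 == 0))
  # mismatched feature configuration is a versioning error
  bad <- assemble_pixel_features(p$ct$slices[, , 2], msk[, , 2],
                                 feature_config(scales = 16))
  expect_error(predict_f4(model, p$ct$slices[, , 2], msk[, , 2],
                          features = bad),
               class = "strokeloc_version_error")
  # single-class labels refuse to train
  expect_error(train_pixel_net(fm, lapply(lb, function(x) x * 0), mks,
                               config = cfg, epochs = 2),
               class = "strokeloc_parameter_error")
})
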