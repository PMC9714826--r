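# Ensemble fusion network: block building, forward pass, training.

fake_features <- function(k = 4, H = 20, W = 20, seed = 1) {
  set.seed(seed)
  lapply(seq_len(k), function(s) {
    msk <- matrix(0L, H, W); msk[3:(H - 2), 3:(W - 2)] <- 1L
    list(F1 = matrix(runif(H * W), H, W) * msk,
         F2 = matrix(runif(H * W), H, W) * msk,
         F3 = matrix(runif(H * W), H, W) * msk,
         F4 = matrix(runif(H * W), H, W) * msk,
         h = msk)
  })
}

test_that("input blocks stack the documented channel layout", {
  feats <- fake_features(4)
  b1 <- build_input_block(feats, 2, 1)
  expect_equal(dim(b1)[3], 5)
  expect_equal(b1[, , 1], feats[[2]]$F1)
  expect_equal(b1[, , 5], feats[[2]]$h * 1)

  b3 <- build_input_block(feats, 1, 3)     # first slice: c-1 replicated
  expect_equal(dim(b3)[3], 15)
  expect_equal(b3[, , 1:5], b3[, , 6:10])  # slice -1 replaced by slice 1
  expect_equal(b3[, , 11], feats[[2]]$F1)

  b5 <- build_input_block(feats, 3, 5)
  expect_equal(dim(b5)[3], 25)
  # centre group occupies channels 11-15
  expect_equal(b5[, , 11], feats[[3]]$F1)
  expect_equal(b5[, , 14], feats[[3]]$F4)
  expect_equal(b5[, , 15], feats[[3]]$h * 1)
  expect_equal(b5[, , 1], feats[[1]]$F1)
  expect_equal(b5[, , 21], feats[[4]]$F1)

  expect_error(build_input_block(feats, 2, 4),
               class = "strokeloc_parameter_error")
  broken <- feats; broken[[2]]$F3 <- NULL
  expect_error(build_input_block(broken, 2, 3),
               class = "strokeloc_dependency_error")
})

test_that("zero weights yield the uniform distribution; probabilities sum to 1", {
  feats <- fake_features(3)
  block <- build_input_block(feats, 2, 3)
  w0 <- strokeloc:::ensemble_init(15, seed = 1)
  w0$l1$K[] <- 0; w0$l1$b[] <- 0; w0$l2$K[] <- 0; w0$l2$b[] <- 0
  p <- ensemble_forward(w0, block)
  expect_true(all(abs(p - 1 / 3) < 1e-12))

  wr <- strokeloc:::ensemble_init(15, seed = 9)
  pr <- ensemble_forward(wr, block)
  sums <- pr[, , 1] + pr[, , 2] + pr[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_error(ensemble_forward(wr, build_input_block(feats, 2, 1)),
               class = "strokeloc_geometry_error")
})

test_that("the 3x3 convolution matches a brute-force oracle", {
  set.seed(4)
  x <- array(rnorm(9 * 9 * 2), c(9, 9, 2))
  K <- matrix(rnorm(3 * 3 * 2 * 1), 18, 1)
  y <- strokeloc:::cpp_conv2d_fw(x, K, 0.3, 3L, 3L, 1L, 1L)$y
  k1 <- array(K[, 1], c(3, 3, 2))
  ref <- oracle_conv2d(x[, , 1], k1[, , 1]) +
         oracle_conv2d(x[, , 2], k1[, , 2]) + 0.3
  expect_lt(max(abs(y[, , 1] - ref)), 1e-6)
})

test_that("a constant volume makes every block group identical", {
  feats <- fake_features(3)
  feats[[1]] <- feats[[2]]; feats[[3]] <- feats[[2]]
  b3 <- build_input_block(feats, 2, 3)
  b1 <- build_input_block(feats, 2, 1)
  expect_equal(b3[, , 1:5], b3[, , 11:15])
  expect_equal(b3[, , 6:10], unclass(b1)[, , 1:5])
})

test_that("the ensemble memorizes one phantom and trains deterministically", {
  p <- tiny_case(seed = 14L, delta = 20)
  msk <- extract_brain_mask_volume(p$ct)
  labels3 <- (p$truth > 0) * 2L + (msk > 0) * (p$truth == 0)
  # idealized feature maps: noisy copies of the truth
  set.seed(2)
  feats <- lapply(1:3, function(k) {
    base <- p$truth[, , k] + matrix(rnorm(48 * 48, 0, 0.15), 48, 48)
    list(F1 = base * (msk[, , k] > 0), F2 = base * (msk[, , k] > 0),
         F3 = base * (msk[, , k] > 0), F4 = base * (msk[, , k] > 0),
         h = msk[, , k])
  })
  blocks <- lapply(1:3, function(k) build_input_block(feats, k, 3))
  labs <- lapply(1:3, function(k) labels3[, , k])
  msks <- lapply(1:3, function(k) msk[, , k])
  w1 <- train_ensemble(blocks, labs, msks, epochs = 8, lr = 5e-3, seed = 3L)
  w2 <- train_ensemble(blocks, labs, msks, epochs = 8, lr = 5e-3, seed = 3L)
  expect_identical(w1$l1$K, w2$l1$K)
  expect_identical(w1$manifest$train_loss, w2$manifest$train_loss)

  pv <- predict_volume(w1, feats, 3)
  acc <- mean(vapply(1:3, function(k) {
    inm <- msk[, , k] > 0
    mean((pv$L[, , k][inm] >= 0.5) == (p$truth[, , k][inm] > 0))
  }, numeric(1)))
  expect_gte(acc, 0.95)
  # out-of-mask infarct probability is exactly zero
  expect_true(all(pv$L[msk == 0] == 0))
  expect_equal(dim(pv$L)[3], 3)

  # loss decreases overall and rarely ticks up between epochs
  tl <- w1$manifest$train_loss
  expect_lt(tl[length(tl)], tl[1])
  expect_lte(sum(diff(tl) > 0), 1)
})

test_that("single-class training data is refused", {
  feats <- fake_features(2)
  blocks <- lapply(1:2, function(k) build_input_block(feats, k, 1))
  msks <- lapply(feats, `[[`, "h")
  labs <- lapply(msks, function(m) m * 1L)   # all class 1
  expect_error(train_ensemble(blocks, labs, msks, epochs = 1),
               class = "strokeloc_parameter_error")
})
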