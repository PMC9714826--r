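# Thresholding, hemisphere selection, majority-rule cells, metrics, IoU,
# and the leave-one-out bookkeeping.

test_that("probability thresholding uses the >= boundary and is monotone", {
  L <- matrix(c(0, 0.2, 0.5, 0.9), 2, 2)
  b <- threshold_probability(L, 0.5)
  expect_equal(as.vector(b), c(0L, 0L, 1L, 1L))   # 0.5 counts as positive
  expect_true(all(threshold_probability(L * 0, 0.5) == 0))
  set.seed(3)
  Lr <- matrix(runif(400), 20, 20)
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(t) sum(threshold_probability(Lr, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(threshold_probability(Lr, 1.5),
               class = "strokeloc_parameter_error")
})

test_that("hemisphere selection keeps the side with the largest component", {
  m <- array(0L, c(20, 20, 2))
  m[5:14, 2:6, 1] <- 1L            # 50-px component on the left
  out <- select_hemisphere(m, midline_col = 9.5)
  expect_equal(as.vector(out), as.vector(m))   # left side untouched
  expect_equal(attr(out, "side_kept"), "left")

  # scattered specks on the right lose against one big left component
  m2 <- m
  m2[cbind(c(3, 7, 11, 15, 18), c(14, 16, 18, 13, 15), 1)] <- 1L
  out2 <- select_hemisphere(m2, 9.5)
  expect_true(all(out2[, 11:20, ] == 0))
  expect_equal(sum(out2), 50)

  # winning-side positives are untouched
  expect_identical(out2[, 1:10, ], m2[, 1:10, ])

  # exact symmetric tie -> image-left by convention
  m3 <- array(0L, c(10, 10, 1))
  m3[3:5, 2:4, 1] <- 1L
  m3[3:5, 7:9, 1] <- 1L
  out3 <- select_hemisphere(m3, 4.5)
  expect_equal(attr(out3, "side_kept"), "left")
  expect_true(all(out3[, 6:10, ] == 0))

  # empty input passes through
  e <- select_hemisphere(array(0L, c(8, 8, 1)), 3.5)
  expect_equal(attr(e, "side_kept"), "none")
  expect_true(all(e == 0))
})

test_that("majority-rule cells follow the strict-majority tie rule", {
  full <- matrix(1L, 32, 32)
  expect_equal(as.vector(cell_majority_labels(full, 32)), 1L)

  m <- matrix(0L, 32, 32)
  m[seq_len(512)] <- 1L            # exactly half
  expect_equal(as.vector(cell_majority_labels(m, 32)), 0L)
  m[513] <- 1L                     # one over half
  expect_equal(as.vector(cell_majority_labels(m, 32)), 1L)

  set.seed(8)
  for (rep in 1:5) {
    r <- matrix(as.integer(runif(48 * 40) < runif(1, 0.3, 0.7)), 48, 40)
    for (cs in c(8, 16, 32))
      expect_identical(unclass(cell_majority_labels(r, cs))[, , drop = TRUE],
                       oracle_majority(r, cs))
  }
})

test_that("metrics follow the confusion-matrix definitions exactly", {
  # TP=2, FP=1, FN=1 worked example
  pred <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  truth <- matrix(c(1, 1, 0, 1, 0, 0), 2, 3)
  m <- compute_metrics(pred, truth)
  expect_equal(m$TP, 2); expect_equal(m$FP, 1); expect_equal(m$FN, 1)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 4 / 6)

  perfect <- compute_metrics(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)

  # undefined 0/0 cases are NA, not zero
  none <- compute_metrics(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(is.na(none$precision))
  expect_true(is.na(none$recall))

  expect_error(compute_metrics(matrix(0, 2, 2), matrix(0, 3, 2)),
               class = "strokeloc_geometry_error")

  set.seed(12)
  for (rep in 1:10) {
    p <- random_mask(rep, 12, 12, 0.4)
    t <- random_mask(rep + 100, 12, 12, 0.4)
    v <- random_mask(rep + 200, 12, 12, 0.8) > 0
    got <- compute_metrics(p, t, valid = v)
    ora <- oracle_confusion(p, t, v)
    expect_equal(c(TP = got$TP, FP = got$FP, FN = got$FN, TN = got$TN), ora)
  }
})

test_that("IoU matches its set definition including empty conventions", {
  a <- matrix(0L, 20, 20)
  sq1 <- matrix(0L, 20, 20); sq1[1:10, 1:10] <- 1L
  sq2 <- matrix(0L, 20, 20); sq2[1:10, 6:15] <- 1L
  expect_equal(compute_iou(sq1, sq1), 1)
  expect_equal(compute_iou(sq1, 1L - sq1), 0)
  expect_equal(compute_iou(sq1, sq2), 50 / 150)
  expect_equal(compute_iou(a, a), 1)     # both empty
  expect_equal(compute_iou(sq1, a), 0)   # one empty
  set.seed(5)
  for (rep in 1:10) {
    x <- random_mask(rep + 300, 16, 16, 0.3)
    y <- random_mask(rep + 400, 16, 16, 0.3)
    expect_equal(compute_iou(x, y), oracle_iou(x, y))
  }
})

test_that("speckle on the contralateral side is removed, raising precision", {
  ok <- 0
  for (s in 1:20) {
    p <- tiny_case(seed = 500L + s, side = if (s %% 2) "left" else "right")
    msk <- extract_brain_mask_volume(p$ct)
    mid <- mask_midline(msk)
    set.seed(s)
    noisy <- p$truth
    W <- dim(noisy)[2]
    opp <- if (s %% 2) ((floor(mid) + 3):(W - 3)) else (3:(ceiling(mid) - 3))
    for (k in seq_len(dim(noisy)[3])) {
      specks <- cbind(sample(3:(dim(noisy)[1] - 3), 6, TRUE),
                      sample(opp, 6, TRUE))
      sl <- noisy[, , k]; sl[specks] <- 1L; noisy[, , k] <- sl
    }
    before <- sum(noisy & p$truth) / sum(noisy)
    post <- select_hemisphere(noisy, mid)
    after <- sum(post & p$truth) / max(sum(post), 1)
    ok <- ok + (after >= before)
  }
  expect_gte(ok / 20, 0.9)
})

test_that("leave-one-out bookkeeping tests each case exactly once", {
  ds <- lapply(c(61L, 62L, 63L), function(s)
    tiny_case(seed = s, delta = 20, side = if (s %% 2) "left" else "right"))
  cfg <- micro_config()
  res <- suppressWarnings(leave_one_out(ds, cfg, master_seed = 5L))
  expect_length(res$reports, 3)
  expect_equal(vapply(res$reports, `[[`, numeric(1), "fold"), 1:3)
  accs <- vapply(res$reports, `[[`, numeric(1), "accuracy")
  expect_equal(res$aggregate$accuracy, mean(accs), tolerance = 1e-12)
  expect_error(leave_one_out(ds[1], cfg), class = "strokeloc_parameter_error")
})

test_that("training on a copy of the test case scores at least as well", {
  ds <- lapply(c(71L, 72L), function(s)
    tiny_case(seed = s, delta = 6, side = if (s %% 2) "left" else "right"))
  cfg <- micro_config()
  honest <- suppressWarnings(leave_one_out(ds, cfg, master_seed = 9L))
  leaky <- suppressWarnings(leave_one_out(c(ds, ds), cfg, master_seed = 9L))
  expect_gte(mean(vapply(leaky$reports, `[[`, numeric(1), "iou_pixel")),
             mean(vapply(honest$reports, `[[`, numeric(1), "iou_pixel")))
})
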