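# Skull stripping, convex hulls, rigid hull registration, label transfer.

test_that("skull stripping keeps only the largest soft-tissue component", {
  # all-air slice -> empty, flagged
  m0 <- extract_brain_mask(matrix(-1000, 32, 32))
  expect_equal(sum(m0), 0)
  expect_true(attr(m0, "empty"))

  # two blobs: 500-px rectangle and 80-px rectangle; only the large survives
  sl <- matrix(-1000, 64, 64)
  sl[11:35, 11:30] <- 35        # 25x20 = 500 px
  sl[51:58, 51:60] <- 35        # 8x10 = 80 px
  m <- extract_brain_mask(sl)
  expect_equal(sum(m), 500)
  expect_true(all(m[51:58, 51:60] == 0))

  # bone and air are never foreground
  p <- tiny_case(seed = 2L)
  msk <- extract_brain_mask(p$ct$slices[, , 2])
  expect_true(all(p$ct$slices[, , 2][msk > 0] < 300))
  expect_true(all(p$ct$slices[, , 2][msk > 0] > -200))
})

test_that("interior holes are filled and re-masking is idempotent", {
  sl <- matrix(-1000, 40, 40)
  sl[10:30, 10:30] <- 35
  sl[18:22, 18:22] <- -500      # air pocket inside the tissue
  m <- extract_brain_mask(sl)
  expect_equal(sum(m), 21 * 21) # hole filled
  # idempotence: masking the slice with its own mask and re-extracting
  sl2 <- sl; sl2[m == 0] <- -1000
  m2 <- extract_brain_mask(sl2)
  expect_identical(as.vector(m2 == 1), as.vector(m == 1))
})

test_that("convex hull contains the mask and is minimal on rectangles", {
  m <- matrix(0L, 30, 30); m[6:20, 9:25] <- 1L
  h <- convex_hull(m)
  expect_false(attr(h, "degenerate"))
  expect_equal(nrow(h), 4)
  expect_setequal(paste(h[, 1], h[, 2]),
                  c("5 8", "5 24", "19 8", "19 24"))

  # degenerate single pixel is flagged
  m1 <- matrix(0L, 10, 10); m1[4, 7] <- 1L
  h1 <- convex_hull(m1)
  expect_true(attr(h1, "degenerate"))
  expect_error(convex_hull(matrix(0L, 5, 5)),
               class = "strokeloc_geometry_error")

  # random blob: every mask pixel inside (or on) the hull, hull area >= mask
  set.seed(9)
  m2 <- matrix(0L, 40, 40)
  ctr <- cbind(sample(10:30, 200, TRUE), sample(10:30, 200, TRUE))
  m2[ctr] <- 1L
  h2 <- convex_hull(m2)
  pts <- which(m2 == 1, arr.ind = TRUE) - 1
  # grow the hull infinitesimally about its centroid so vertices and edge
  # points count as inside under the strict ray-casting oracle
  cen <- colMeans(unclass(h2))
  grown <- sweep(unclass(h2), 2, cen) * (1 + 1e-6)
  grown <- sweep(grown, 2, cen, `+`)
  inside <- apply(pts, 1, oracle_in_polygon, verts = grown)
  expect_true(all(inside))
  # the hull covers at least the mask's own area
  expect_gte(strokeloc:::hull_area(h2), sum(m2))
})

test_that("hull registration is exact on identical hulls and recovers known transforms", {
  p <- tiny_case(seed = 3L, theta = 0, tx = 0, ty = 0)
  m <- extract_brain_mask(p$ct$slices[, , 2])
  h <- convex_hull(m)
  tf <- register_hulls(h, h)
  expect_lt(abs(tf$theta), 0.26)
  expect_lt(abs(tf$tx) + abs(tf$ty), 0.76)
  expect_lt(attr(tf, "objective") / strokeloc:::hull_area(h), 0.01)

  for (s in c(101L, 202L)) {
    set.seed(s)
    th <- runif(1, -8, 8); tx <- runif(1, -8, 8); ty <- runif(1, -8, 8)
    p <- generate_phantom(phantom_spec(theta = th, tx = tx, ty = ty,
                                       seed = s))
    pp <- preprocess_case(p$ct, p$labels)
    expect_lt(abs(pp$transform$theta - th), 0.5)
    expect_lt(abs(pp$transform$tx - tx), 0.5)
    expect_lt(abs(pp$transform$ty - ty), 0.5)
  }
})

test_that("registration of rotationally symmetric hulls is flagged", {
  m <- matrix(0L, 64, 64)
  rows <- matrix(0:63, 64, 64); cols <- t(rows)
  m[(rows - 31.5)^2 + (cols - 31.5)^2 <= 20^2] <- 1L
  h <- convex_hull(m)
  tf <- register_hulls(h, h)
  expect_true(tf$low_confidence)
  expect_equal(tf$theta, 0, tolerance = 1e-8)
})

test_that("registration never does worse than the identity transform", {
  for (s in 1:5) {
    p <- tiny_case(seed = s, theta = runif(1, -8, 8), tx = runif(1, -6, 6),
                   ty = runif(1, -6, 6))
    mask <- extract_brain_mask(p$ct$slices[, , 2])
    hf <- convex_hull(mask)
    hm <- convex_hull(p$labels$labels[, , 2] > 0)
    tf <- register_hulls(hf, hm)
    # identity under the same scale pre-normalisation
    c_f <- (attr(hf, "frame_shape") - 1) / 2
    c_m <- (attr(hm, "frame_shape") - 1) / 2
    vm0 <- sweep(unclass(hm), 2, c_m) %*% diag(tf$scale)
    vm0 <- sweep(vm0, 2, c_f, `+`)
    obj_id <- strokeloc:::cpp_symdiff_obj(unclass(hf), vm0, 0.25)
    expect_lte(attr(tf, "objective"), obj_id + 1e-9)
  }
})

test_that("label transfer matches a brute-force inverse mapping", {
  p <- tiny_case(seed = 4L)
  lab <- p$labels
  # identity transform: unchanged
  id <- rigid_transform(center_moving = c(23.5, 19.5),
                        center_fixed = c(23.5, 19.5))
  out <- transfer_labels(lab, id, dim(lab$labels)[1:2])
  expect_identical(out$labels, lab$labels)

  # pure translation by 5 rows: exact shift, via independent enumeration
  tr <- rigid_transform(ty = 5, center_moving = c(0, 0),
                        center_fixed = c(0, 0))
  out2 <- transfer_labels(lab, tr, dim(lab$labels)[1:2])
  H <- dim(lab$labels)[1]
  brute <- array(0L, dim(lab$labels))
  for (k in seq_len(dim(lab$labels)[3]))
    for (i in seq_len(H))
      if (i - 5 >= 1) brute[i, , k] <- lab$labels[i - 5, , k]
  expect_identical(out2$labels[, seq_len(dim(lab$labels)[2]), ],
                   brute[, seq_len(dim(lab$labels)[2]), ])

  # label alphabet is preserved (subset plus background)
  expect_true(all(unique(as.vector(out2$labels)) %in%
                  c(0L, unique(as.vector(lab$labels)))))

  # everything pushed off-grid -> all background, flagged
  far <- rigid_transform(tx = 500, center_moving = c(0, 0),
                         center_fixed = c(0, 0))
  out3 <- transfer_labels(lab, far, dim(lab$labels)[1:2])
  expect_true(attr(out3, "all_background"))
})
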