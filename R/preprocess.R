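# Brain-mask extraction, convex-hull rigid registration of the perfusion
# frame onto the CT grid, and nearest-neighbour label transfer.

#' Construct a 2-D rigid transform
#'
#' Maps points of the moving (perfusion/label) frame into the fixed (CT)
#' frame as `q = R(theta) %*% (scale * (p - center_moving)) + center_fixed +
#' c(ty, tx)`, with points as 0-based `(row, col)` pixel-centre coordinates
#' and `R` the rotation by `theta` degrees in the (row, col) plane.
#'
#' @param theta Rotation in degrees.
#' @param tx,ty Translations in pixels along columns (`tx`) and rows (`ty`).
#' @param scale Length-1 or length-2 positive scale `(row, col)`.
#' @param center_moving,center_fixed Frame centres, 0-based `(row, col)`.
#' @param low_confidence Flag set by [register_hulls()] when the objective
#'   was flat (e.g. rotationally symmetric hulls).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0, scale = c(1, 1),
                            center_moving = c(0, 0), center_fixed = c(0, 0),
                            low_confidence = FALSE) {
  scale <- rep(as.numeric(scale), length.out = 2)
  if (any(scale <= 0)) stop_parameter("scale must be positive")
  structure(list(theta = theta, tx = tx, ty = ty, scale = scale,
                 center_moving = as.numeric(center_moving),
                 center_fixed = as.numeric(center_fixed),
                 low_confidence = isTRUE(low_confidence)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> theta %.2f deg, t (%.2f, %.2f) px, scale (%.3f, %.3f)%s\n",
    x$theta, x$tx, x$ty, x$scale[1], x$scale[2],
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf A [rigid_transform].
#' @param pts n x 2 matrix of `(row, col)` points in the moving frame.
#' @return n x 2 matrix of points in the fixed frame.
#' @export
apply_rigid <- function(tf, pts) {
  pts <- matrix(pts, ncol = 2)
  th <- tf$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  centered <- sweep(pts, 2, tf$center_moving) %*% diag(tf$scale)
  out <- centered %*% t(R)
  sweep(out, 2, tf$center_fixed + c(tf$ty, tf$tx), `+`)
}

# 2x3 affine mapping fixed-frame (target) pixels back to the moving frame,
# as used by the nearest-neighbour warp.
rigid_inverse_affine <- function(tf) {
  th <- tf$theta * pi / 180
  Rinv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  M <- diag(1 / tf$scale) %*% Rinv
  v <- -M %*% (tf$center_fixed + c(tf$ty, tf$tx)) + tf$center_moving
  cbind(M, v)
}

#' Extract the brain mask from a CT slice
#'
#' Skull stripping by HU thresholds: bone (`HU >= bone_hu`) and air
#' (`HU <= air_hu`) are excluded, only the largest remaining 4-connected
#' soft-tissue component is kept, and interior holes are filled. An all-air
#' slice yields an empty mask with attribute `empty = TRUE`.
#'
#' @param slice 2-D matrix in HU.
#' @param bone_hu,air_hu Exclusion thresholds in HU.
#' @return Integer 0/1 matrix of the same shape (class `brain_mask`), with
#'   attributes `area_px` and `empty`.
#' @export
extract_brain_mask <- function(slice, bone_hu = 300, air_hu = -200) {
  cand <- as_imat(slice < bone_hu & slice > air_hu)
  lab <- cpp_label4(cand)
  if (max(lab) == 0L) {
    mask <- as_imat(matrix(0L, nrow(slice), ncol(slice)))
  } else {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
    mask <- as_imat(lab == keep)
    mask <- cpp_fill_holes(mask)
  }
  structure(mask, class = c("brain_mask", class(mask)),
            area_px = sum(mask), empty = sum(mask) == 0L)
}

#' Extract brain masks for a whole volume
#'
#' @param volume A [ct_volume].
#' @inheritParams extract_brain_mask
#' @return 3-D integer 0/1 array `[row, col, slice]`.
#' @export
extract_brain_mask_volume <- function(volume, bone_hu = 300, air_hu = -200) {
  d <- dim(volume$slices)
  out <- array(0L, d)
  for (k in seq_len(d[3]))
    out[, , k] <- extract_brain_mask(volume$slices[, , k], bone_hu, air_hu)
  out
}

#' Convex hull of a binary mask
#'
#' Minimal convex polygon containing the centres of all foreground pixels,
#' with vertices ordered counter-clockwise in `(row, col)` coordinates
#' (0-based). A single-pixel mask yields a degenerate hull flagged via the
#' `degenerate` attribute.
#'
#' @param mask Binary matrix.
#' @return `hull_polygon`: n x 2 matrix of `(row, col)` vertices with
#'   attribute `frame_shape`.
#' @export
convex_hull <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_geometry("convex hull of an empty mask")
  pts <- cbind(idx[, 1] - 1, idx[, 2] - 1)  # 0-based (row, col)
  if (nrow(unique(pts)) < 3) {
    return(structure(matrix(pts[1, ], ncol = 2), degenerate = TRUE,
                     frame_shape = dim(mask), class = "hull_polygon"))
  }
  h <- chull(pts[, 2], pts[, 1])   # (x = col, y = row)
  verts <- pts[h, , drop = FALSE]
  # enforce counter-clockwise orientation in (row, col)
  n <- nrow(verts)
  area2 <- sum(verts[, 1] * verts[c(2:n, 1), 2] -
               verts[c(2:n, 1), 1] * verts[, 2])
  if (area2 < 0) verts <- verts[n:1, , drop = FALSE]
  structure(verts, degenerate = FALSE, frame_shape = dim(mask),
            class = "hull_polygon")
}

hull_area <- function(verts) {
  n <- nrow(verts)
  abs(sum(verts[, 1] * verts[c(2:n, 1), 2] -
          verts[c(2:n, 1), 1] * verts[, 2])) / 2
}

#' Register two convex hulls rigidly
#'
#' Finds `(scale, theta, tx, ty)` minimising the area of the symmetric
#' difference between the fixed hull and the transformed moving hull. The
#' anisotropic scale is pre-set from the ratio of hull bounding boxes (the
#' two frames may have different aspect ratios); a coarse grid over
#' `theta` in `[-15, 15]` degrees step 1 and `tx, ty` in `[-20, 20]` px step
#' 2 is then refined locally. The objective valley curves jointly in
#' `(theta, t)`, so the refinement runs a Nelder-Mead polish from each of
#' the best coarse candidates (optionally including the two scale factors)
#' and finishes with a coordinate polish at 0.1 degree / 0.25 px
#' resolution. Ties are broken toward the smallest `|theta|`, then smallest
#' `|tx| + |ty|`. A flat coarse objective sets the `low_confidence` flag on
#' the result.
#'
#' @param hull_fixed,hull_moving `hull_polygon` objects from [convex_hull()].
#' @param theta_range,t_range Coarse search half-ranges (degrees, px).
#' @param refine_scale Also refine the two scale factors locally.
#' @return A [rigid_transform] with attribute `objective` (residual
#'   symmetric-difference area, px^2).
#' @export
register_hulls <- function(hull_fixed, hull_moving, theta_range = 15,
                           t_range = 20, refine_scale = TRUE) {
  if (isTRUE(attr(hull_fixed, "degenerate")) ||
      isTRUE(attr(hull_moving, "degenerate")))
    stop_geometry("cannot register degenerate hulls")
  shape_f <- attr(hull_fixed, "frame_shape")
  shape_m <- attr(hull_moving, "frame_shape")
  c_f <- (shape_f - 1) / 2
  c_m <- (shape_m - 1) / 2
  bb_f <- apply(hull_fixed, 2, function(v) diff(range(v)))
  bb_m <- apply(hull_moving, 2, function(v) diff(range(v)))
  scale <- bb_f / bb_m
  vf <- unclass(hull_fixed)
  vm0 <- sweep(unclass(hull_moving), 2, c_m) %*% diag(scale)

  thetas <- seq(-theta_range, theta_range, by = 1)
  txs <- seq(-t_range, t_range, by = 2)
  tys <- seq(-t_range, t_range, by = 2)
  obj <- cpp_reg_grid(vf, vm0, thetas, txs, tys, c_f[1], c_f[2], 1.0)
  best <- min(obj)
  # tie-break: smallest |theta|, then |tx|+|ty|
  cand <- which(obj <= best + 1e-9, arr.ind = TRUE)
  pref <- order(abs(thetas[cand[, 1]]),
                abs(txs[cand[, 2]]) + abs(tys[cand[, 3]]))
  pick <- cand[pref[1], ]
  # flat objective (e.g. rotationally symmetric hulls): rotation barely
  # moves the objective at the optimal translation, relative to the spread
  # the whole grid shows; quantisation noise keeps the profile above zero,
  # hence the relative criterion
  theta_profile <- obj[, pick[2], pick[3]]
  flat <- diff(range(theta_profile)) <=
    0.03 * max(max(obj) - best, .Machine$double.eps)

  eval_par <- function(p) {
    vm <- sweep(unclass(hull_moving), 2, c_m) %*% diag(c(p[4], p[5]))
    th <- p[1] * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    vm <- vm %*% t(R)
    vm[, 1] <- vm[, 1] + c_f[1] + p[3]
    vm[, 2] <- vm[, 2] + c_f[2] + p[2]
    cpp_symdiff_obj(vf, vm, 0.25)
  }
  # local refinement: the objective valley curves jointly in (theta, t),
  # where axis-aligned step halving stalls, so a Nelder-Mead polish runs
  # from each of the best coarse candidates and the best end point wins
  ord_cand <- order(obj)[seq_len(min(4, length(obj)))]
  starts <- lapply(ord_cand, function(ix) {
    id3 <- arrayInd(ix, dim(obj))
    c(thetas[id3[1]], txs[id3[2]], tys[id3[3]], scale[1], scale[2])
  })
  par <- NULL; cur <- Inf
  for (st in starts) {
    fixed_scale <- st[4:5]
    fn <- if (refine_scale) eval_par else
      function(p) eval_par(c(p[1:3], fixed_scale))
    p0 <- if (refine_scale) st else st[1:3]
    opt <- stats::optim(p0, fn, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10,
                                       parscale = if (refine_scale)
                                         c(0.5, 1, 1, 0.01, 0.01)
                                       else c(0.5, 1, 1)))
    cand_par <- if (refine_scale) opt$par else c(opt$par, fixed_scale)
    if (opt$value < cur - 1e-12) { par <- cand_par; cur <- opt$value }
  }
  # final coordinate polish at the documented resolution floors
  steps <- c(0.1, 0.25, 0.25, 0.00125, 0.00125)
  active <- c(TRUE, TRUE, TRUE, refine_scale, refine_scale)
  repeat {
    improved <- FALSE
    for (i in which(active)) {
      for (sgn in c(-1, 1)) {
        trial <- par
        trial[i] <- trial[i] + sgn * steps[i]
        v <- eval_par(trial)
        if (v < cur - 1e-12) {
          par <- trial; cur <- v; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  out <- rigid_transform(theta = unname(par[1]), tx = unname(par[2]),
                         ty = unname(par[3]), scale = unname(par[4:5]),
                         center_moving = c_m, center_fixed = c_f,
                         low_confidence = flat)
  attr(out, "objective") <- cur
  out
}

#' Transfer a label map onto the CT grid
#'
#' Nearest-neighbour resampling of a (misaligned) label map into the CT
#' pixel grid under a rigid transform; target pixels that map outside the
#' source extent get class 0. Per the single-representative-pair convention,
#' one transform is applied to every slice.
#'
#' @param labels A [label_map] in its own (moving) frame.
#' @param transform A [rigid_transform] mapping the moving frame into the
#'   CT frame.
#' @param target_shape Length-2 `(rows, cols)` of the CT grid.
#' @return A [label_map] on the CT grid; attribute `all_background` flags a
#'   transform that pushed every label off-grid.
#' @export
transfer_labels <- function(labels, transform, target_shape) {
  A <- rigid_inverse_affine(transform)
  d <- dim(labels$labels)
  out <- array(0L, c(target_shape, d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- cpp_warp_nn(labels$labels[, , k], A,
                              target_shape[1], target_shape[2], 0L)
  res <- label_map(out, classes = labels$classes)
  attr(res, "all_background") <- all(out == 0L)
  res
}

#' Preprocess a CT / perfusion-label case
#'
#' Runs the full preprocessing chain: per-slice brain masks, convex hulls of
#' the representative mid-stack slice pair, rigid hull registration, and
#' label transfer onto the CT grid. With `per_slice = TRUE` a transform is
#' estimated for every slice pair instead of the single representative one.
#'
#' @param ct A [ct_volume].
#' @param labels A [label_map] in the perfusion frame (same slice count).
#' @param bone_hu,air_hu Skull-stripping thresholds.
#' @param per_slice Estimate one transform per slice pair.
#' @return List with `mask` (3-D 0/1 array), `transform` (representative
#'   [rigid_transform]), `labels_ct` (transferred [label_map]).
#' @export
preprocess_case <- function(ct, labels, bone_hu = 300, air_hu = -200,
                            per_slice = FALSE) {
  d <- dim(ct$slices)
  if (dim(labels$labels)[3] != d[3])
    stop_geometry("CT and label map must have the same slice count")
  mask <- extract_brain_mask_volume(ct, bone_hu, air_hu)
  rep_k <- ceiling(d[3] / 2)
  hull_ct <- convex_hull(mask[, , rep_k])
  hull_lb <- convex_hull(labels$labels[, , rep_k] > 0)
  tf <- register_hulls(hull_ct, hull_lb)
  if (!per_slice) {
    labels_ct <- transfer_labels(labels, tf, d[1:2])
  } else {
    out <- array(0L, c(d[1:2], d[3]))
    for (k in seq_len(d[3])) {
      hk_ct <- convex_hull(mask[, , k])
      hk_lb <- convex_hull(labels$labels[, , k] > 0)
      tk <- register_hulls(hk_ct, hk_lb)
      lk <- label_map(labels$labels[, , k], classes = labels$classes)
      out[, , k] <- transfer_labels(lk, tk, d[1:2])$labels[, , 1]
    }
    labels_ct <- label_map(out, classes = labels$classes)
  }
  list(mask = mask, transform = tf, labels_ct = labels_ct)
}

#' Collapse transferred label classes into training targets
#'
#' Produces the 3-class training target {0 = background, 1 = normal tissue,
#' 2 = infarct}. `positive = "core+penumbra"` (default) counts both the
#' infarct core (class 2) and hypoperfused tissue (class 3) as infarct;
#' `"core"` counts only the core.
#'
#' @param labels_ct Transferred [label_map] on the CT grid.
#' @param mask 3-D brain-mask array.
#' @param positive `"core+penumbra"` or `"core"`.
#' @return 3-D integer array of classes {0, 1, 2}.
#' @export
collapse_labels <- function(labels_ct, mask,
                            positive = c("core+penumbra", "core")) {
  positive <- match.arg(positive)
  lab <- labels_ct$labels
  pos <- if (positive == "core") lab == 2L else lab >= 2L
  out <- array(0L, dim(lab))
  out[mask > 0] <- 1L
  out[mask > 0 & pos] <- 2L
  out
}
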