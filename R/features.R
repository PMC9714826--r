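# Hand-crafted pixel features: contralateral (C), local (K) and global (G)
# intensity statistics concatenated into a per-pixel vector, plus the small
# fully-connected network that turns the vector into the F4 infarct
# probability map.
#
# The hemispheric midline is the vertical line through the column centroid
# of the brain mask, computed per slice; an image-centre midline would fail
# for off-centre brains.

#' Feature configuration
#'
#' @param cell_size Contralateral cell size in px (square cells).
#' @param scales Sliding-window sizes for the local features. Windows are
#'   centred symmetrically: a nominal size `w` spans `w/2` pixels to either
#'   side of the centre pixel (`(w+1)^2` pixels), keeping every statistic
#'   mirror-symmetric. The single-scale configuration `scales = 16` yields
#'   the literal 13-component pixel vector; the default concatenates all
#'   three scales (21 components).
#' @param bilateral_sigma_s,bilateral_sigma_r Bilateral filter spatial sigma
#'   (px) and range sigma (HU).
#' @return A `feature_config` list with the derived channel names.
#' @export
feature_config <- function(cell_size = 16, scales = c(8, 16, 32),
                           bilateral_sigma_s = 3, bilateral_sigma_r = 10) {
  if (any(scales < 2) || any(scales %% 2 != 0))
    stop_parameter("window scales must be even and >= 2")
  nm <- c(paste0("C_own_", c("max", "mean", "median")),
          paste0("C_contra_", c("max", "mean", "median")),
          unlist(lapply(sort(scales), function(w)
            paste0("K", w, "_", c("max", "mean", "median", "bilat")))),
          paste0("G_", c("max", "mean", "median")))
  structure(list(cell_size = as.integer(cell_size),
                 scales = as.integer(sort(scales)),
                 bilateral_sigma_s = bilateral_sigma_s,
                 bilateral_sigma_r = bilateral_sigma_r,
                 channel_names = nm),
            class = "feature_config")
}

#' Column centroid of a mask
#'
#' The hemispheric midline, as a 0-based continuous column coordinate.
#' @param mask Binary matrix (or 3-D stack, pooled over slices).
#' @return Numeric scalar; `NA` for an empty mask.
#' @export
mask_midline <- function(mask) {
  if (length(dim(mask)) == 3L) {
    tot <- 0; cnt <- 0
    for (k in seq_len(dim(mask)[3])) {
      idx <- which(mask[, , k] != 0, arr.ind = TRUE)
      tot <- tot + sum(idx[, 2] - 1)
      cnt <- cnt + nrow(idx)
    }
    return(if (cnt == 0) NA_real_ else tot / cnt)
  }
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  mean(idx[, 2] - 1)
}

#' Per-cell intensity statistics
#'
#' Divides the slice into `cell_size` x `cell_size` cells (edge cells may be
#' smaller) and computes max, mean and median of the HU over in-mask pixels
#' of each cell. Cells without in-mask pixels carry `NA` (imputed with the
#' global in-mask mean downstream).
#'
#' @param slice 2-D HU matrix.
#' @param mask 2-D 0/1 mask of the same shape.
#' @param cell_size Cell edge length in px; must not exceed the slice.
#' @return `cell_grid`: list of matrices `max`, `mean`, `median`,
#'   `occupancy` (rows x cols of cells) plus the cell edges.
#' @export
cell_statistics <- function(slice, mask, cell_size = 16) {
  H <- nrow(slice); W <- ncol(slice)
  if (cell_size > H || cell_size > W)
    stop_parameter("cell_size larger than the slice")
  if (!all(dim(slice) == dim(mask)))
    stop_geometry("slice and mask shapes differ")
  nr <- ceiling(H / cell_size); nc <- ceiling(W / cell_size)
  mx <- mn <- md <- matrix(NA_real_, nr, nc)
  occ <- matrix(0L, nr, nc)
  for (ci in seq_len(nr)) {
    rr <- ((ci - 1) * cell_size + 1):min(ci * cell_size, H)
    for (cj in seq_len(nc)) {
      cs <- ((cj - 1) * cell_size + 1):min(cj * cell_size, W)
      v <- slice[rr, cs][mask[rr, cs] > 0]
      occ[ci, cj] <- length(v)
      if (length(v)) {
        mx[ci, cj] <- max(v)
        mn[ci, cj] <- mean(v)
        md[ci, cj] <- median(v)
      }
    }
  }
  structure(list(max = mx, mean = mn, median = md, occupancy = occ,
                 cell_size = cell_size, slice_shape = c(H, W)),
            class = "cell_grid")
}

#' Contralateral cell of a cell column
#'
#' Mirrors the horizontal centre of cell column `col_index` across the
#' midline and returns the column index of the cell containing the mirrored
#' centre (same cell row). Returns `NA` when the mirror falls outside the
#' grid.
#'
#' @param col_index 1-based cell column index.
#' @param grid A `cell_grid` (for the cell geometry).
#' @param midline_col Midline as a 0-based column coordinate.
#' @return 1-based cell column index or `NA`.
#' @export
contralateral_pair <- function(col_index, grid, midline_col) {
  cs <- grid$cell_size
  W <- grid$slice_shape[2]
  nc <- ncol(grid$max)
  lo <- (col_index - 1) * cs
  hi <- min(col_index * cs, W) - 1
  center <- (lo + hi) / 2
  mirrored <- 2 * midline_col - center
  if (mirrored < 0 || mirrored > W - 1) return(NA_integer_)
  j <- floor(mirrored / cs) + 1
  if (j < 1 || j > nc) return(NA_integer_)
  as.integer(j)
}

#' Local sliding-window features
#'
#' For every pixel and every window scale: max, mean and median of the
#' in-mask HU over the symmetric window centred at the pixel (clipped at
#' the image border), plus the value of the bilateral-filtered slice at the pixel
#' (the filter is applied once per slice). Windows with no in-mask pixel
#' are imputed with the global in-mask mean.
#'
#' @param slice,mask 2-D HU matrix and 0/1 mask.
#' @param config A [feature_config()].
#' @return List per scale of `max`/`mean`/`median` matrices plus `bilat`.
#' @export
local_window_features <- function(slice, mask, config = feature_config()) {
  mask <- as_imat(mask > 0)
  gmean <- mean(slice[mask > 0])
  bil <- cpp_bilateral(slice, mask, config$bilateral_sigma_s,
                       config$bilateral_sigma_r)
  bil[mask == 0] <- if (is.finite(gmean)) gmean else 0
  out <- list(bilat = bil, scales = list())
  for (w in config$scales) {
    st <- cpp_window_stats(slice, mask, radius = w %/% 2)
    for (nm in c("max", "mean", "median"))
      st[[nm]][is.na(st[[nm]])] <- gmean
    out$scales[[as.character(w)]] <- st
  }
  out
}

#' Global in-mask intensity features
#'
#' @param slice,mask 2-D HU matrix and 0/1 mask.
#' @return Named vector `(max, mean, median)` over in-mask pixels.
#' @export
global_features <- function(slice, mask) {
  v <- slice[mask > 0]
  if (length(v) == 0) stop_parameter("global features of an empty mask")
  c(max = max(v), mean = mean(v), median = median(v))
}

#' Assemble the per-pixel feature vector map
#'
#' Concatenation order: own-cell contralateral statistics (3), mirrored-cell
#' statistics (3), local window statistics per ascending scale (4 each),
#' global statistics (3). With the default three scales the vector has 21
#' components; with a single scale, 13.
#'
#' @param slice,mask 2-D HU matrix and 0/1 mask.
#' @param config A [feature_config()].
#' @return 3-D array `(H, W, n_features)` with dimnames on the channel
#'   axis; every value is finite.
#' @export
assemble_pixel_features <- function(slice, mask, config = feature_config()) {
  H <- nrow(slice); W <- ncol(slice)
  mask <- as_imat(mask > 0)
  nfeat <- length(config$channel_names)
  out <- array(0, c(H, W, nfeat))
  if (sum(mask) == 0) {
    dimnames(out) <- list(NULL, NULL, config$channel_names)
    return(out)
  }
  g <- global_features(slice, mask)
  grid <- cell_statistics(slice, mask, config$cell_size)
  mid <- mask_midline(mask)
  cs <- config$cell_size
  # per-pixel cell indices
  ci <- (seq_len(H) - 1) %/% cs + 1
  cj <- (seq_len(W) - 1) %/% cs + 1
  contra_j <- vapply(seq_len(ncol(grid$max)), contralateral_pair,
                     integer(1), grid = grid, midline_col = mid)
  imput <- function(m) { m[is.na(m)] <- g[["mean"]]; m }
  own_mx <- imput(grid$max); own_mn <- imput(grid$mean)
  own_md <- imput(grid$median)
  ctr_mx <- ctr_mn <- ctr_md <- matrix(g[["mean"]], nrow(grid$max),
                                       ncol(grid$max))
  ok <- !is.na(contra_j)
  ctr_mx[, ok] <- own_mx[, contra_j[ok], drop = FALSE]
  ctr_mn[, ok] <- own_mn[, contra_j[ok], drop = FALSE]
  ctr_md[, ok] <- own_md[, contra_j[ok], drop = FALSE]
  # but a contralateral cell that exists yet is empty must impute, not copy
  # (own_* already imputed, so this is consistent)
  out[, , 1] <- own_mx[ci, cj]
  out[, , 2] <- own_mn[ci, cj]
  out[, , 3] <- own_md[ci, cj]
  out[, , 4] <- ctr_mx[ci, cj]
  out[, , 5] <- ctr_mn[ci, cj]
  out[, , 6] <- ctr_md[ci, cj]
  lw <- local_window_features(slice, mask, config)
  ch <- 6
  for (w in config$scales) {
    st <- lw$scales[[as.character(w)]]
    out[, , ch + 1] <- st$max
    out[, , ch + 2] <- st$mean
    out[, , ch + 3] <- st$median
    out[, , ch + 4] <- lw$bilat
    ch <- ch + 4
  }
  out[, , ch + 1] <- g[["max"]]
  out[, , ch + 2] <- g[["mean"]]
  out[, , ch + 3] <- g[["median"]]
  dimnames(out) <- list(NULL, NULL, config$channel_names)
  out
}

#' Train the pixel-wise feature network (F4)
#'
#' Samples in-mask pixels (balanced across classes by weighting), learns
#' per-feature standardisation on the training data only, and trains a
#' small fully-connected softmax network with class-weighted cross-entropy,
#' Adam and early stopping on a validation split.
#'
#' @param feature_maps List of `(H, W, d)` arrays from
#'   [assemble_pixel_features()], one per slice.
#' @param labels List of 2-D class maps (0/1/2) aligned with the slices.
#' @param masks List of 2-D 0/1 brain masks.
#' @param config The [feature_config()] used to build the features.
#' @param epochs,lr,hidden,max_pixels_per_slice Training controls.
#' @param seed Integer seed.
#' @return An `f4_model` (network weights, standardisation, config).
#' @export
train_pixel_net <- function(feature_maps, labels, masks,
                            config = feature_config(), epochs = 25,
                            lr = 1e-3, hidden = c(64, 32),
                            max_pixels_per_slice = 800, seed = 1L) {
  set.seed(seed)
  X <- list(); y <- list()
  for (i in seq_along(feature_maps)) {
    inm <- which(masks[[i]] > 0)
    if (length(inm) == 0) next
    take <- if (length(inm) > max_pixels_per_slice)
      sample(inm, max_pixels_per_slice) else inm
    fm <- feature_maps[[i]]
    d <- dim(fm)[3]
    Xi <- matrix(fm, ncol = d)[take, , drop = FALSE]
    X[[length(X) + 1]] <- Xi
    y[[length(y) + 1]] <- as.integer(labels[[i]][take] == 2L) + 1L
  }
  X <- do.call(rbind, X)
  y <- unlist(y)
  if (length(unique(y)) < 2)
    stop_parameter("training labels are single-class")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  fit <- mlp_train(Xs, y, hidden = hidden, n_classes = 2, epochs = epochs,
                   lr = lr)
  structure(list(layers = fit$layers, mu = mu, sd = sdev, config = config,
                 train_loss = fit$train_loss, seed = seed,
                 n_features = ncol(X)),
            class = "f4_model")
}

#' Predict the F4 feature map for a slice
#'
#' @param model A trained `f4_model`.
#' @param slice,mask 2-D HU matrix and 0/1 mask.
#' @param features Optional precomputed [assemble_pixel_features()] array.
#' @return Matrix of per-pixel infarct probability in `[0, 1]`, zero outside
#'   the mask.
#' @export
predict_f4 <- function(model, slice, mask, features = NULL) {
  if (!inherits(model, "f4_model"))
    stop_state("predict_f4 needs a trained f4_model")
  if (is.null(features))
    features <- assemble_pixel_features(slice, mask, model$config)
  d <- dim(features)[3]
  if (d != model$n_features)
    stop_strokeloc(sprintf(
      "feature configuration mismatch: model trained on %d features, got %d",
      model$n_features, d), "strokeloc_version_error")
  H <- dim(features)[1]; W <- dim(features)[2]
  inm <- which(mask > 0)
  out <- matrix(0, H, W)
  if (length(inm)) {
    Xm <- matrix(features, ncol = d)[inm, , drop = FALSE]
    Xs <- sweep(sweep(Xm, 2, model$mu), 2, model$sd, "/")
    out[inm] <- mlp_predict(model$layers, Xs)[, 2]
  }
  out
}
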