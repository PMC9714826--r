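# Ensemble fusion: a two-layer convolutional network over blocks of feature
# maps from 1, 3 or 5 neighbouring slices. Layer 1: 64 kernels 3x3, stride
# 1, ReLU, with the centre-slice brain mask multiplicatively gating the
# activations; layer 2: 3 kernels 1x1, ReLU, then a softmax over the three
# class channels {background, normal tissue, infarct}. The infarct channel
# is the probability map L.

#' Stack feature maps of neighbouring slices into an input block
#'
#' Channels are ordered by slice `c - floor(b/2) .. c + floor(b/2)`, within
#' each slice `[F1, F2, F3, F4, h]`. Out-of-range neighbours are replaced by
#' the nearest existing slice (edge replication).
#'
#' @param features List (one entry per slice) of named lists with matrices
#'   `F1, F2, F3, F4, h`.
#' @param c Centre slice index (1-based).
#' @param block_size 1, 3, or 5.
#' @return 3-D array `(H, W, 5 * block_size)` of class `input_block` with
#'   attributes `block_size` and `center_index`.
#' @export
build_input_block <- function(features, c, block_size = 3) {
  if (!block_size %in% c(1, 3, 5))
    stop_parameter("block_size must be 1, 3 or 5")
  k <- length(features)
  chan <- c("F1", "F2", "F3", "F4", "h")
  for (s in seq_len(k)) {
    miss <- setdiff(chan, names(features[[s]]))
    if (length(miss))
      stop_strokeloc(sprintf("slice %d lacks feature map(s): %s", s,
                             paste(miss, collapse = ", ")),
                     "strokeloc_dependency_error")
  }
  half <- (block_size - 1) / 2
  slice_ids <- pmin(pmax(c + (-half):half, 1), k)
  H <- nrow(features[[c]]$F1); W <- ncol(features[[c]]$F1)
  block <- array(0, c(H, W, 5 * block_size))
  i <- 0
  for (s in slice_ids) {
    for (ch in chan) {
      i <- i + 1
      block[, , i] <- features[[s]][[ch]]
    }
  }
  structure(block, block_size = block_size, center_index = c,
            class = c("input_block", "array"))
}

# The ReLU placed before the softmax can clamp a class logit to zero over
# the whole image at initialisation; that class would then never receive
# gradient. A clearly positive logit bias makes every class channel live at
# the start (train_ensemble additionally restarts from a shifted seed if a
# run still begins dead).
ensemble_init <- function(in_channels, seed = 1L) {
  set.seed(seed)
  list(l1 = conv_param(3, 3, in_channels, 64),
       l2 = conv_param(1, 1, 64, 3, bias0 = 0.25))
}

#' Forward pass of the ensemble network
#'
#' @param weights Ensemble weights from [train_ensemble()] (or
#'   `ensemble_init`); layer 1 has 64 3x3 kernels, layer 2 has 3 1x1 kernels.
#' @param block An input block from [build_input_block()].
#' @param center_mask Optional 0/1 matrix; the centre-slice brain mask that
#'   gates layer-1 activations. Defaults to the block's own mask channel.
#' @return 3-D array `(H, W, 3)` of per-pixel class probabilities
#'   (background, normal, infarct); they sum to 1 at every pixel.
#' @export
ensemble_forward <- function(weights, block, center_mask = NULL) {
  bs <- attr(block, "block_size") %||% (dim(block)[3] / 5)
  if (dim(block)[3] != nrow(weights$l1$K) / 9)
    stop_geometry(sprintf("block has %d channels but weights expect %d",
                          dim(block)[3], nrow(weights$l1$K) / 9))
  if (is.null(center_mask)) {
    mid <- (ceiling(bs / 2) - 1) * 5 + 5
    center_mask <- block[, , mid]
  }
  z1 <- conv_fw(weights$l1, unclass(block))
  a1 <- relu(z1)
  a1 <- sweep(a1, c(1, 2), (center_mask > 0) * 1, `*`)
  z2 <- conv_fw(weights$l2, a1)
  a2 <- relu(z2)
  softmax_channels(a2)
}

ensemble_loss_grad <- function(weights, block, labels3, center_mask,
                               class_weights) {
  fw1 <- conv_fw(weights$l1, unclass(block), return_col = TRUE)
  z1 <- fw1$y
  a1 <- relu(z1)
  gate <- (center_mask > 0) * 1
  a1g <- sweep(a1, c(1, 2), gate, `*`)
  fw2 <- conv_fw(weights$l2, a1g, return_col = TRUE)
  z2 <- fw2$y
  a2 <- relu(z2)
  probs <- softmax_channels(a2)
  H <- dim(block)[1]; W <- dim(block)[2]
  inm <- center_mask > 0
  wmat <- matrix(0, H, W)
  wmat[inm] <- class_weights[labels3[inm] + 1L]
  wsum <- max(sum(wmat), 1e-12)
  pick <- matrix(1, H, W)
  for (cl in 0:2) {
    sel <- labels3 == cl
    pick[sel] <- probs[, , cl + 1][sel]
  }
  loss <- -sum(wmat[inm] * log(pmax(pick[inm], 1e-12))) / wsum
  da2 <- probs
  for (cl in 0:2) da2[, , cl + 1] <- da2[, , cl + 1] - (labels3 == cl)
  da2 <- sweep(da2, c(1, 2), wmat / wsum, `*`)
  dz2 <- da2; dz2[z2 <= 0] <- 0
  bw2 <- conv_bw(weights$l2, a1g, dz2, col = fw2$col)
  da1 <- sweep(bw2$dx, c(1, 2), gate, `*`)
  dz1 <- da1; dz1[z1 <= 0] <- 0
  bw1 <- conv_bw(weights$l1, unclass(block), dz1, want_dx = FALSE,
                 col = fw1$col)
  list(loss = loss,
       grads = list(l1 = list(K = bw1$dW, b = bw1$db),
                    l2 = list(K = bw2$dW, b = bw2$db)))
}

#' Train the ensemble network
#'
#' Class-weighted cross-entropy over in-mask pixels, Adam, one block per
#' step, shuffled per epoch; class weights default to inverse pixel
#' frequency computed on the training data.
#'
#' @param blocks List of input blocks from [build_input_block()].
#' @param labels List of 2-D centre-slice class maps (0/1/2).
#' @param masks List of 2-D centre-slice brain masks.
#' @param epochs,lr Training schedule.
#' @param sample_frac Fraction of the training blocks visited per epoch
#'   (stochastic subsampling, seeded; 1 scans every block).
#' @param seed Seed for initialisation and shuffling.
#' @param class_weights Optional length-3 weights for classes 0..2.
#' @return `ensemble_weights`: layer parameters plus a training manifest
#'   (seed, block size, channel count, loss curve).
#' @export
train_ensemble <- function(blocks, labels, masks, epochs = 8, lr = 2e-3,
                           sample_frac = 1, seed = 1L,
                           class_weights = NULL) {
  if (length(blocks) == 0) stop_parameter("no training blocks")
  in_ch <- dim(blocks[[1]])[3]
  present <- unique(unlist(lapply(seq_along(blocks), function(i)
    unique(labels[[i]][masks[[i]] > 0]))))
  if (length(present) < 2)
    stop_parameter("training labels are single-class within the mask")
  if (is.null(class_weights)) {
    freq <- c(0, 0, 0)
    for (i in seq_along(blocks)) {
      inm <- masks[[i]] > 0
      for (cl in 0:2) freq[cl + 1] <- freq[cl + 1] + sum(labels[[i]][inm] == cl)
    }
    class_weights <- sum(freq) / (3 * pmax(freq, 1))
  }
  n_per_ep <- max(1L, ceiling(sample_frac * length(blocks)))
  dead_level <- log(3)   # loss of a network emitting uniform probabilities
  probe <- seq_len(min(3L, length(blocks)))
  # liveness of the current weights: the loss must have left the uniform
  # plateau AND the infarct channel must be the argmax somewhere it was
  # taught. The infarct channel can die alone (its pre-softmax ReLU clamped
  # everywhere) while the other classes keep the loss low, so the check is
  # per class, not loss-only. A collapse in the very last steps would be
  # invisible in epoch-average losses, hence the probe on final weights.
  is_alive <- function(weights) {
    final_loss <- mean(vapply(probe, function(i)
      ensemble_loss_grad(weights, blocks[[i]], labels[[i]], masks[[i]],
                         class_weights)$loss, numeric(1)))
    if (final_loss >= dead_level - 1e-3) return(FALSE)
    scan <- unique(round(seq(1, length(blocks), length.out = 10)))
    for (i in scan) {
      sel <- labels[[i]] == 2L & masks[[i]] > 0
      if (!any(sel)) next
      p <- ensemble_forward(list(l1 = weights$l1, l2 = weights$l2),
                            blocks[[i]], center_mask = masks[[i]])
      if (max(p[, , 3][sel]) > 0.5) return(TRUE)
    }
    FALSE
  }
  for (attempt in 0:5) {
    attempt_seed <- seed + 1000L * attempt
    attempt_lr <- lr / 2^(attempt %/% 2)
    weights <- ensemble_init(in_ch, seed = attempt_seed)
    st <- adam_init(weights)
    losses <- numeric(0)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(blocks))[seq_len(n_per_ep)]
      acc <- 0
      for (i in ord) {
        lg <- ensemble_loss_grad(weights, blocks[[i]], labels[[i]],
                                 masks[[i]], class_weights)
        up <- adam_step(weights, pad_conv_grads(weights, lg$grads), st,
                        lr = attempt_lr)
        weights <- up$params
        st <- up$state
        acc <- acc + lg$loss
      }
      losses <- c(losses, acc / n_per_ep)
      # a dead start stays dead: abort after the first epoch instead of
      # spending the remaining epochs before restarting
      if (ep == 1L && epochs > 1L && !is_alive(weights)) break
    }
    if (length(losses) == epochs && is_alive(weights)) break
  }
  structure(list(l1 = weights$l1, l2 = weights$l2,
                 manifest = list(seed = seed, attempt_seed = attempt_seed,
                                 in_channels = in_ch,
                                 block_size = in_ch / 5,
                                 class_weights = class_weights,
                                 train_loss = losses)),
            class = "ensemble_weights")
}

#' Predict infarct probability maps for a volume
#'
#' @param weights Trained [train_ensemble()] weights.
#' @param features Per-slice feature-map list as for [build_input_block()].
#' @param block_size 1, 3, or 5 (must match the weights).
#' @return List with `probs` (list of `(H, W, 3)` arrays, one per slice) and
#'   `L` (3-D array of the infarct-probability channel, zero outside the
#'   brain mask).
#' @export
predict_volume <- function(weights, features, block_size = 3) {
  k <- length(features)
  H <- nrow(features[[1]]$F1); W <- ncol(features[[1]]$F1)
  L <- array(0, c(H, W, k))
  probs <- vector("list", k)
  for (c in seq_len(k)) {
    block <- build_input_block(features, c, block_size)
    p <- ensemble_forward(weights, block, center_mask = features[[c]]$h)
    p3 <- p[, , 3] * (features[[c]]$h > 0)
    probs[[c]] <- p
    L[, , c] <- p3
  }
  list(probs = probs, L = L)
}
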