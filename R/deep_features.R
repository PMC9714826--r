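# Deep feature-map pathway: pluggable slice-to-feature-map extractors. The
# built-in extractor is a miniature encoder-decoder (strided-convolution
# encoder, dilated middle block, bilinear-upsampling decoder with a skip
# connection) trained for per-pixel infarct classification; its infarct
# probability channel is the exported feature map. Three variants differing
# in width multiplier and seed play the role of independent backbone
# networks whose feature diversity the ensemble exploits.

#' Specify a feature extractor
#'
#' @param name Identifier (`"f1"`, `"f2"`, `"f3"`, or free-form).
#' @param width_mult Channel-width multiplier of the encoder-decoder.
#' @param output_channels Number of feature channels exported per slice
#'   (the built-in extractor exposes its infarct-probability channel).
#' @param seed Integer seed for weight initialisation and data shuffling.
#' @return A `extractor_spec` list.
#' @export
extractor_spec <- function(name = "f1", width_mult = 1, output_channels = 1L,
                           seed = 1L) {
  if (width_mult <= 0) stop_parameter("width_mult must be positive")
  if (output_channels < 1) stop_parameter("output_channels must be >= 1")
  structure(list(name = name, width_mult = width_mult,
                 output_channels = as.integer(output_channels),
                 seed = as.integer(seed)),
            class = "extractor_spec")
}

#' Built-in extractor variants
#'
#' Three differently sized / seeded encoder-decoders standing in for three
#' distinct backbone networks.
#' @return List of three [extractor_spec]s.
#' @export
default_extractor_specs <- function() {
  list(extractor_spec("f1", width_mult = 0.75, seed = 101L),
       extractor_spec("f2", width_mult = 1.00, seed = 202L),
       extractor_spec("f3", width_mult = 1.25, seed = 303L))
}

extractor_widths <- function(width_mult) {
  w <- function(x) max(2L, as.integer(round(x * width_mult)))
  c(c0 = w(8), c1 = w(12), c2 = w(16), head = w(12))
}

extractor_init <- function(spec) {
  w <- extractor_widths(spec$width_mult)
  set.seed(spec$seed)
  params <- list(
    c0 = conv_param(3, 3, 2, w["c0"]),
    c1 = conv_param(3, 3, w["c0"], w["c1"], stride = 2L),
    c2 = conv_param(3, 3, w["c1"], w["c2"], stride = 2L),
    d1 = conv_param(3, 3, w["c2"], w["c2"], dil = 2L),
    d2 = conv_param(3, 3, w["c2"], w["c2"], dil = 4L),
    h1 = conv_param(3, 3, w["c2"] + w["c0"], w["head"]),
    h2 = conv_param(1, 1, w["head"], 2)
  )
  list(spec = spec, params = params)
}

# normalise a HU slice for network input; out-of-mask pixels are zeroed
normalize_ct_slice <- function(slice, mask) {
  z <- (pmin(pmax(slice, -10), 90) - 35) / 15
  z * (mask > 0)
}

extractor_input <- function(slice, mask) {
  H <- nrow(slice); W <- ncol(slice)
  x <- array(0, c(H, W, 2))
  x[, , 1] <- normalize_ct_slice(slice, mask)
  x[, , 2] <- (mask > 0) * 1
  x
}

extractor_forward <- function(params, x, keep_cache = FALSE) {
  H <- dim(x)[1]; W <- dim(x)[2]
  kc <- keep_cache
  f0 <- conv_fw(params$c0, x, kc);  z0 <- if (kc) f0$y else f0; a0 <- relu(z0)
  f1 <- conv_fw(params$c1, a0, kc); z1 <- if (kc) f1$y else f1; a1 <- relu(z1)
  f2 <- conv_fw(params$c2, a1, kc); z2 <- if (kc) f2$y else f2; a2 <- relu(z2)
  f3 <- conv_fw(params$d1, a2, kc); z3 <- if (kc) f3$y else f3; a3 <- relu(z3)
  f4 <- conv_fw(params$d2, a3, kc); z4 <- if (kc) f4$y else f4; a4 <- relu(z4)
  up <- cpp_resize_bilinear(a4, H, W)
  cat5 <- array(0, c(H, W, dim(up)[3] + dim(a0)[3]))
  cat5[, , seq_len(dim(up)[3])] <- up
  cat5[, , dim(up)[3] + seq_len(dim(a0)[3])] <- a0
  f5 <- conv_fw(params$h1, cat5, kc); z5 <- if (kc) f5$y else f5; a5 <- relu(z5)
  f6 <- conv_fw(params$h2, a5, kc);   z6 <- if (kc) f6$y else f6
  probs <- softmax_channels(z6)
  out <- list(probs = probs)
  if (keep_cache)
    out$cache <- list(x = x, z0 = z0, a0 = a0, z1 = z1, a1 = a1, z2 = z2,
                      a2 = a2, z3 = z3, a3 = a3, z4 = z4, a4 = a4, up = up,
                      cat5 = cat5, z5 = z5, a5 = a5, z6 = z6,
                      cols = list(c0 = f0$col, c1 = f1$col, c2 = f2$col,
                                  d1 = f3$col, d2 = f4$col, h1 = f5$col,
                                  h2 = f6$col))
  out
}

# class-weighted cross-entropy over in-mask pixels; target: 1 = infarct
extractor_loss_grad <- function(params, x, target, mask, class_weights) {
  fw <- extractor_forward(params, x, keep_cache = TRUE)
  cc <- fw$cache
  probs <- fw$probs
  H <- dim(x)[1]; W <- dim(x)[2]
  wmat <- matrix(0, H, W)
  inm <- mask > 0
  wmat[inm] <- class_weights[target[inm] + 1L]
  wsum <- max(sum(wmat), 1e-12)
  p1 <- probs[, , 2]
  picked <- ifelse(target == 1L, p1, 1 - p1)
  loss <- -sum(wmat[inm] * log(pmax(picked[inm], 1e-12))) / wsum
  dz6 <- probs
  dz6[, , 1] <- dz6[, , 1] - (target == 0L)
  dz6[, , 2] <- dz6[, , 2] - (target == 1L)
  dz6 <- sweep(dz6, c(1, 2), wmat / wsum, `*`)

  g <- list()
  bw6 <- conv_bw(params$h2, cc$a5, dz6, col = cc$cols$h2)
  g$h2 <- list(K = bw6$dW, b = bw6$db)
  da5 <- bw6$dx; da5[cc$z5 <= 0] <- 0
  bw5 <- conv_bw(params$h1, cc$cat5, da5, col = cc$cols$h1)
  g$h1 <- list(K = bw5$dW, b = bw5$db)
  n_up <- dim(cc$up)[3]
  dup <- bw5$dx[, , seq_len(n_up), drop = FALSE]
  da0_skip <- bw5$dx[, , n_up + seq_len(dim(cc$a0)[3]), drop = FALSE]
  da4 <- cpp_resize_bilinear_adj(dup, dim(cc$a4)[1], dim(cc$a4)[2])
  da4[cc$z4 <= 0] <- 0
  bw4 <- conv_bw(params$d2, cc$a3, da4, col = cc$cols$d2)
  g$d2 <- list(K = bw4$dW, b = bw4$db)
  da3 <- bw4$dx; da3[cc$z3 <= 0] <- 0
  bw3 <- conv_bw(params$d1, cc$a2, da3, col = cc$cols$d1)
  g$d1 <- list(K = bw3$dW, b = bw3$db)
  da2 <- bw3$dx; da2[cc$z2 <= 0] <- 0
  bw2 <- conv_bw(params$c2, cc$a1, da2, col = cc$cols$c2)
  g$c2 <- list(K = bw2$dW, b = bw2$db)
  da1 <- bw2$dx; da1[cc$z1 <= 0] <- 0
  bw1 <- conv_bw(params$c1, cc$a0, da1, col = cc$cols$c1)
  g$c1 <- list(K = bw1$dW, b = bw1$db)
  da0 <- bw1$dx + da0_skip
  da0[cc$z0 <= 0] <- 0
  bw0 <- conv_bw(params$c0, cc$x, da0, want_dx = FALSE, col = cc$cols$c0)
  g$c0 <- list(K = bw0$dW, b = bw0$db)
  list(loss = loss, grads = g)
}

#' Train a feature extractor
#'
#' Trains the miniature encoder-decoder for per-pixel infarct classification
#' with class-weighted cross-entropy over in-mask pixels, Adam, one slice
#' per step, shuffled per epoch. Fully deterministic given the spec seed.
#'
#' @param spec An [extractor_spec].
#' @param dataset List of cases; each case needs `ct` ([ct_volume]), `mask`
#'   (3-D 0/1 array) and `labels3` (3-D array of classes 0/1/2).
#' @param epochs,lr Training schedule.
#' @param sample_frac Fraction of the training slices visited per epoch
#'   (stochastic subsampling, seeded; 1 scans every slice).
#' @return An `extractor_model` (parameters + spec + training curve).
#' @export
train_extractor <- function(spec, dataset, epochs = 10, lr = 1e-3,
                            sample_frac = 1) {
  if (length(dataset) == 0) stop_parameter("empty training dataset")
  samples <- list()
  for (case in dataset) {
    for (k in seq_len(dim(case$ct$slices)[3])) {
      samples[[length(samples) + 1]] <- list(
        x = extractor_input(case$ct$slices[, , k], case$mask[, , k]),
        target = as_imat(case$labels3[, , k] == 2L),
        mask = case$mask[, , k])
    }
  }
  n_pos <- sum(vapply(samples, function(s) sum(s$target[s$mask > 0]),
                      numeric(1)))
  n_in <- sum(vapply(samples, function(s) sum(s$mask > 0), numeric(1)))
  freq <- c(n_in - n_pos, n_pos)
  cw <- sum(freq) / (2 * pmax(freq, 1))
  model <- extractor_init(spec)
  st <- adam_init(model$params)
  losses <- numeric(epochs)
  n_per_ep <- max(1L, ceiling(sample_frac * length(samples)))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(samples))[seq_len(n_per_ep)]
    acc <- 0
    for (i in ord) {
      s <- samples[[i]]
      lg <- extractor_loss_grad(model$params, s$x, s$target, s$mask, cw)
      up <- adam_step(model$params, pad_conv_grads(model$params, lg$grads),
                      st, lr = lr)
      model$params <- up$params
      st <- up$state
      acc <- acc + lg$loss
    }
    losses[ep] <- acc / n_per_ep
  }
  structure(list(spec = spec, params = model$params, class_weights = cw,
                 train_loss = losses),
            class = "extractor_model")
}

# align conv grad lists with the parameter structure (NULL for metadata)
pad_conv_grads <- function(params, grads) {
  out <- params
  for (nm in names(params)) {
    g <- grads[[nm]]
    out[[nm]] <- list(K = g$K, b = g$b, kh = NULL, kw = NULL,
                      stride = NULL, dil = NULL)
  }
  out
}

#' Extract a feature map from a slice
#'
#' @param model A trained `extractor_model`.
#' @param slice 2-D HU matrix.
#' @param mask 2-D 0/1 brain mask.
#' @return Matrix of per-pixel infarct probability, zero outside the mask,
#'   same shape as the input.
#' @export
extract_feature_map <- function(model, slice, mask) {
  if (!inherits(model, "extractor_model"))
    stop_state("extract_feature_map needs a trained extractor_model")
  x <- extractor_input(slice, mask)
  probs <- extractor_forward(model$params, x)$probs
  probs[, , 2] * (mask > 0)
}
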