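# Shared neural-network primitives: He initialisation, Adam, a small
# fully-connected classifier (used for the hand-crafted pixel features), and
# thin R wrappers over the C++ convolution / resize kernels. All training
# loops are seeded and single-threaded, so runs are bit-reproducible on one
# platform.

he_init <- function(n_in, n_out, fan_in) {
  matrix(rnorm(n_in * n_out, 0, sqrt(2 / fan_in)), n_in, n_out)
}

conv_param <- function(kh, kw, c_in, c_out, stride = 1L, dil = 1L,
                       bias0 = 0.01) {
  list(K = he_init(kh * kw * c_in, c_out, fan_in = kh * kw * c_in),
       b = rep(bias0, c_out), kh = kh, kw = kw, stride = stride, dil = dil)
}

conv_fw <- function(p, x, return_col = FALSE) {
  out <- cpp_conv2d_fw(x, p$K, p$b, p$kh, p$kw, p$stride, p$dil, return_col)
  if (return_col) out else out$y
}

conv_bw <- function(p, x, dy, want_dx = TRUE, col = NULL) {
  cpp_conv2d_bw(x, p$K, dy, p$kh, p$kw, p$stride, p$dil, want_dx, col)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# softmax over the 3rd dimension of an (H, W, C) cube
softmax_channels <- function(z) {
  C <- dim(z)[3]
  m <- z[, , 1]
  for (c in seq_len(C)[-1]) m <- pmax(m, z[, , c])
  out <- z
  s <- 0
  for (c in seq_len(C)) {
    out[, , c] <- exp(z[, , c] - m)
    s <- s + out[, , c]
  }
  for (c in seq_len(C)) out[, , c] <- out[, , c] / s
  out
}

# --- Adam over an arbitrary nested parameter list --------------------------

adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# Adam must skip the non-numeric conv metadata (kh, kw, stride, dil); grads
# lists carry NULL there, handled above. Helper to build grad skeletons:
null_grads <- function(params) {
  rapply(params, function(x) NULL, how = "replace")
}

# --- small fully-connected softmax classifier ------------------------------

mlp_init <- function(d_in, hidden = c(64, 32), n_classes = 2) {
  dims <- c(d_in, hidden, n_classes)
  layers <- vector("list", length(dims) - 1)
  for (i in seq_along(layers)) {
    layers[[i]] <- list(W = he_init(dims[i], dims[i + 1], fan_in = dims[i]),
                        b = rep(0, dims[i + 1]))
  }
  # zero-init the softmax layer: an untrained net outputs uniform
  # probabilities, and gradients still flow (no ReLU on the output)
  n <- length(layers)
  layers[[n]]$W <- layers[[n]]$W * 0
  layers
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  n <- length(layers)
  for (i in seq_len(n)) {
    z <- acts[[i]] %*% layers[[i]]$W
    z <- sweep(z, 2, layers[[i]]$b, `+`)
    acts[[i + 1]] <- if (i < n) relu(z) else z
  }
  logits <- acts[[n + 1]]
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, acts = acts)
}

# y: integer classes 1..k; w: per-sample weights
mlp_loss_grad <- function(layers, X, y, w) {
  fw <- mlp_forward(layers, X)
  n <- nrow(X)
  k <- ncol(fw$probs)
  picked <- fw$probs[cbind(seq_len(n), y)]
  loss <- -sum(w * log(pmax(picked, 1e-12))) / sum(w)
  dlogits <- fw$probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits * (w / sum(w))
  grads <- vector("list", length(layers))
  delta <- dlogits
  for (i in rev(seq_along(layers))) {
    grads[[i]] <- list(W = crossprod(fw$acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1) {
      delta <- delta %*% t(layers[[i]]$W)
      delta[fw$acts[[i]] <= 0] <- 0
    }
  }
  list(loss = loss, grads = grads)
}

# Mini-batch Adam training with optional early stopping on a held-out
# validation split. Deterministic given the RNG state at entry.
mlp_train <- function(X, y, hidden = c(64, 32), n_classes = 2,
                      epochs = 30, batch = 1024, lr = 1e-3,
                      class_weights = NULL, val_frac = 0.15, patience = 5) {
  n <- nrow(X)
  if (length(unique(y)) < 2) stop_parameter("training labels are single-class")
  if (is.null(class_weights)) {
    freq <- tabulate(y, n_classes)
    class_weights <- sum(freq) / (n_classes * pmax(freq, 1))
  }
  idx <- sample.int(n)
  n_val <- if (val_frac > 0) max(1L, floor(n * val_frac)) else 0L
  val <- head(idx, n_val)
  tr <- setdiff(idx, val)
  layers <- mlp_init(ncol(X), hidden, n_classes)
  st <- adam_init(layers)
  best <- list(layers = layers, val = Inf, epoch = 0L)
  losses <- numeric(0)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- tr[sample.int(length(tr))]
    ep_loss <- 0; nb <- 0
    for (s in seq(1, length(ord), by = batch)) {
      b <- ord[s:min(s + batch - 1, length(ord))]
      lg <- mlp_loss_grad(layers, X[b, , drop = FALSE], y[b],
                          class_weights[y[b]])
      up <- adam_step(layers, lg$grads, st, lr = lr)
      layers <- up$params
      st <- up$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    losses <- c(losses, ep_loss / nb)
    if (n_val > 0) {
      vp <- mlp_forward(layers, X[val, , drop = FALSE])$probs
      vl <- -mean(class_weights[y[val]] *
                  log(pmax(vp[cbind(seq_along(val), y[val])], 1e-12)))
      if (vl < best$val - 1e-6) {
        best <- list(layers = layers, val = vl, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    } else {
      best <- list(layers = layers, val = NA_real_, epoch = ep)
    }
  }
  list(layers = best$layers, train_loss = losses, val_loss = best$val,
       class_weights = class_weights, epochs_run = length(losses))
}

mlp_predict <- function(layers, X) {
  mlp_forward(layers, X)$probs
}
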