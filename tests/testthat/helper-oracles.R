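# Independent brute-force oracles used to verify the package's statistics,
# convolutions and metrics. Written straight from the definitions, not
# sharing code paths with the implementation.

oracle_window_stats <- function(slice, mask, w) {
  r <- w %/% 2
  H <- nrow(slice); W <- ncol(slice)
  mx <- mn <- md <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      rr <- max(1, i - r):min(H, i + r)
      cc <- max(1, j - r):min(W, j + r)
      v <- slice[rr, cc][mask[rr, cc] > 0]
      if (length(v)) {
        mx[i, j] <- max(v); mn[i, j] <- mean(v); md[i, j] <- median(v)
      }
    }
  }
  list(max = mx, mean = mn, median = md)
}

oracle_cell_stats <- function(slice, mask, cs) {
  H <- nrow(slice); W <- ncol(slice)
  nr <- ceiling(H / cs); nc <- ceiling(W / cs)
  mx <- mn <- md <- matrix(NA_real_, nr, nc)
  for (a in seq_len(nr)) {
    for (b in seq_len(nc)) {
      rr <- ((a - 1) * cs + 1):min(a * cs, H)
      cc <- ((b - 1) * cs + 1):min(b * cs, W)
      v <- slice[rr, cc][mask[rr, cc] > 0]
      if (length(v)) {
        mx[a, b] <- max(v); mn[a, b] <- mean(v); md[a, b] <- median(v)
      }
    }
  }
  list(max = mx, mean = mn, median = md)
}

# plain 2-D cross-correlation with zero padding ("same"), one in / one out
# channel, written as four nested loops straight from the definition
oracle_conv2d <- function(x, k, bias = 0) {
  H <- nrow(x); W <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  out <- matrix(bias, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- bias
      for (a in seq_len(kh)) {
        for (b in seq_len(kw)) {
          ii <- i + a - 1 - ph; jj <- j + b - 1 - pw
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
            acc <- acc + x[ii, jj] * k[a, b]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

oracle_majority <- function(mask2d, cs) {
  H <- nrow(mask2d); W <- ncol(mask2d)
  nr <- ceiling(H / cs); nc <- ceiling(W / cs)
  out <- matrix(0L, nr, nc)
  for (a in seq_len(nr)) {
    for (b in seq_len(nc)) {
      rr <- ((a - 1) * cs + 1):min(a * cs, H)
      cc <- ((b - 1) * cs + 1):min(b * cs, W)
      n <- length(rr) * length(cc)
      out[a, b] <- as.integer(sum(mask2d[rr, cc] > 0) > n / 2)
    }
  }
  out
}

oracle_confusion <- function(pred, truth, valid) {
  p <- as.vector(pred)[as.vector(valid)]
  t <- as.vector(truth)[as.vector(valid)]
  c(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
    FN = sum(p == 0 & t == 1), TN = sum(p == 0 & t == 0))
}

oracle_iou <- function(a, b) {
  u <- sum(a > 0 | b > 0)
  if (u == 0) 1 else sum(a > 0 & b > 0) / u
}

# ray-casting point-in-polygon (vertices as (row, col), 0-based points)
oracle_in_polygon <- function(pt, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- verts[i, 1]; xi <- verts[i, 2]
    yj <- verts[j, 1]; xj <- verts[j, 2]
    if ((yi > pt[1]) != (yj > pt[1])) {
      xint <- xj + (pt[1] - yj) / (yi - yj) * (xi - xj)
      if (pt[2] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}
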