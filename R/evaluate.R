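# Thresholding, hemisphere postprocessing, and the cell-wise evaluation
# protocol: 32x32 majority-rule subsampling, precision / recall / F1 /
# accuracy over cells, and pixel-level intersection-over-union.

#' Threshold a probability map
#'
#' A pixel is positive iff `L >= tau` (boundary values count as positive)
#' and it lies inside the brain mask.
#'
#' @param L 3-D (or 2-D) infarct-probability array.
#' @param tau Threshold in (0, 1); default 0.5.
#' @param mask Optional brain mask of the same shape.
#' @return Integer 0/1 array of the same shape, attribute `tau`.
#' @export
threshold_probability <- function(L, tau = 0.5, mask = NULL) {
  if (tau <= 0 || tau >= 1) stop_parameter("tau must lie in (0, 1)")
  out <- as_imat(L >= tau)
  if (!is.null(mask)) out <- as_imat(out * (mask > 0))
  attr(out, "tau") <- tau
  out
}

# largest 4-connected component size per slice within a column range
largest_component_size <- function(mask2d) {
  lab <- cpp_label4(as_imat(mask2d))
  if (max(lab) == 0L) return(0L)
  max(tabulate(lab[lab > 0L]))
}

#' Hemisphere selection postprocessing
#'
#' Infarcts are one-sided; isolated speckle on the opposite side is noise.
#' For each side of the midline the largest 4-connected positive component
#' is found per slice and the sizes are summed across slices; all positives
#' on the losing side are zeroed (one side is kept for the whole volume).
#' Ties go to the side with the larger total positive count, then to
#' image-left.
#'
#' @param mask_bin 3-D (or 2-D) 0/1 positive mask.
#' @param midline_col Midline as 0-based column coordinate, typically
#'   [mask_midline()] of the brain mask.
#' @return 0/1 array of the same shape; attribute `side_kept` is `"left"`,
#'   `"right"` or `"none"` (empty input).
#' @export
select_hemisphere <- function(mask_bin, midline_col) {
  d2 <- length(dim(mask_bin)) == 2L
  m <- if (d2) array(mask_bin, c(dim(mask_bin), 1)) else mask_bin
  W <- dim(m)[2]
  left_cols <- which((seq_len(W) - 1) < midline_col)
  right_cols <- setdiff(seq_len(W), left_cols)
  if (sum(m) == 0) {
    out <- if (d2) mask_bin else m
    attr(out, "side_kept") <- "none"
    return(out)
  }
  score <- c(left = 0, right = 0)
  total <- c(left = 0, right = 0)
  for (k in seq_len(dim(m)[3])) {
    sl <- m[, , k]
    lft <- sl; lft[, right_cols] <- 0L
    rgt <- sl; rgt[, left_cols] <- 0L
    score["left"] <- score["left"] + largest_component_size(lft)
    score["right"] <- score["right"] + largest_component_size(rgt)
    total["left"] <- total["left"] + sum(lft)
    total["right"] <- total["right"] + sum(rgt)
  }
  side <- if (score["left"] > score["right"]) "left"
          else if (score["right"] > score["left"]) "right"
          else if (total["left"] > total["right"]) "left"
          else if (total["right"] > total["left"]) "right"
          else "left"
  drop_cols <- if (side == "left") right_cols else left_cols
  for (k in seq_len(dim(m)[3])) m[, drop_cols, k] <- 0L
  out <- if (d2) m[, , 1] else m
  out <- as_imat(out)
  attr(out, "side_kept") <- side
  out
}

#' Majority-rule cell subsampling
#'
#' Tiles each slice with `cell_size` x `cell_size` cells (edge cells may be
#' smaller) and labels a cell positive iff strictly more than half of its
#' pixels are positive; an exact half is negative.
#'
#' @param pixel_mask 2-D or 3-D 0/1 array.
#' @param cell_size Cell edge in px, default 32.
#' @param mask Optional brain mask; adds an `occupancy` attribute (in-mask
#'   pixel count per cell) used to exclude background cells from metrics.
#' @return 0/1 cell-label array (2-D or 3-D matching the input), class
#'   `cell_label_grid`.
#' @export
cell_majority_labels <- function(pixel_mask, cell_size = 32, mask = NULL) {
  if (cell_size < 1) stop_parameter("cell_size must be >= 1")
  one <- function(m2, msk2) {
    H <- nrow(m2); W <- ncol(m2)
    nr <- ceiling(H / cell_size); nc <- ceiling(W / cell_size)
    lab <- matrix(0L, nr, nc); occ <- matrix(0L, nr, nc)
    for (ci in seq_len(nr)) {
      rr <- ((ci - 1) * cell_size + 1):min(ci * cell_size, H)
      for (cj in seq_len(nc)) {
        cs <- ((cj - 1) * cell_size + 1):min(cj * cell_size, W)
        n <- length(rr) * length(cs)
        lab[ci, cj] <- as.integer(sum(m2[rr, cs]) * 2L > n)
        if (!is.null(msk2)) occ[ci, cj] <- sum(msk2[rr, cs] > 0)
      }
    }
    list(lab = lab, occ = occ)
  }
  if (length(dim(pixel_mask)) == 2L) {
    r <- one(pixel_mask, mask)
    out <- r$lab
    if (!is.null(mask)) attr(out, "occupancy") <- r$occ
  } else {
    K <- dim(pixel_mask)[3]
    r1 <- one(pixel_mask[, , 1], if (!is.null(mask)) mask[, , 1])
    out <- array(0L, c(dim(r1$lab), K))
    occ <- array(0L, c(dim(r1$lab), K))
    out[, , 1] <- r1$lab; occ[, , 1] <- r1$occ
    for (k in seq_len(K)[-1]) {
      r <- one(pixel_mask[, , k], if (!is.null(mask)) mask[, , k])
      out[, , k] <- r$lab; occ[, , k] <- r$occ
    }
    if (!is.null(mask)) attr(out, "occupancy") <- occ
  }
  class(out) <- c("cell_label_grid", class(out))
  out
}

#' Cell-wise classification metrics
#'
#' Confusion counts over cells with at least one in-mask pixel (background
#' cells are excluded so they cannot inflate accuracy), and the derived
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 * precision * recall / (precision + recall), and
#' accuracy = (TP+TN)/(TP+TN+FP+FN). Zero-denominator metrics are reported
#' as `NA` (undefined), not 0.
#'
#' @param pred,truth Cell-label arrays of the same shape
#'   ([cell_majority_labels()]).
#' @param valid Optional logical array marking cells that enter the counts;
#'   defaults to the `occupancy` attribute of `truth` (if present) being
#'   positive, else all cells.
#' @return List: TP, FP, FN, TN, accuracy, precision, recall, f1.
#' @export
compute_metrics <- function(pred, truth, valid = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop_geometry("prediction and truth grids differ in shape")
  if (is.null(valid)) {
    occ <- attr(truth, "occupancy")
    valid <- if (!is.null(occ)) occ > 0 else rep(TRUE, length(truth))
  }
  p <- as.vector(pred)[as.vector(valid)]
  t <- as.vector(unclass(truth))[as.vector(valid)]
  TP <- sum(p == 1 & t == 1); FP <- sum(p == 1 & t == 0)
  FN <- sum(p == 0 & t == 1); TN <- sum(p == 0 & t == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(TP, TP + FP)
  recall <- safe(TP, TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(TP = TP, FP = FP, FN = FN, TN = TN,
       accuracy = safe(TP + TN, TP + TN + FP + FN),
       precision = precision, recall = recall, f1 = f1)
}

#' Intersection over union
#'
#' `|A intersect B| / |A union B|` over pixels (or any same-shape binary
#' arrays). Both empty is defined as 1; exactly one empty gives 0.
#'
#' @param pred,truth Binary arrays of identical shape.
#' @return IoU in `[0, 1]`.
#' @export
compute_iou <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop_geometry("shapes differ")
  uni <- sum(pred > 0 | truth > 0)
  if (uni == 0) return(1)
  sum(pred > 0 & truth > 0) / uni
}

#' Evaluate one case
#'
#' Applies the cell-wise protocol (majority-rule subsampling at
#' `cell_size`, confusion counts over in-mask cells) plus pixel IoU; cell
#' IoU over positive cells is also reported.
#'
#' At desk-scale image sizes a 32 px cell can dwarf a small lesion and leave
#' the cell-level confusion matrix without positives, so pixel-level
#' precision and recall are reported alongside.
#'
#' @param pred_bin,truth_bin 3-D 0/1 pixel masks.
#' @param brain_mask 3-D 0/1 brain mask.
#' @param cell_size Cell edge for subsampling (default 32).
#' @return List of metrics (cell metrics, `iou_pixel`, `iou_cell`,
#'   `precision_pixel`, `recall_pixel`).
#' @export
evaluate_case <- function(pred_bin, truth_bin, brain_mask, cell_size = 32) {
  pc <- cell_majority_labels(pred_bin, cell_size)
  tc <- cell_majority_labels(truth_bin, cell_size, mask = brain_mask)
  m <- compute_metrics(pc, tc)
  m$iou_pixel <- compute_iou(pred_bin, truth_bin)
  m$iou_cell <- compute_iou(unclass(pc), unclass(tc))
  tp_px <- sum(pred_bin > 0 & truth_bin > 0)
  m$precision_pixel <- if (sum(pred_bin > 0) == 0) NA_real_ else
    tp_px / sum(pred_bin > 0)
  m$recall_pixel <- if (sum(truth_bin > 0) == 0) NA_real_ else
    tp_px / sum(truth_bin > 0)
  m
}
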