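# Seeded synthetic head phantoms: an elliptical brain of soft-tissue HU
# inside a high-HU skull ring, with a subtle one-sided hypodense lesion
# contiguous across slices, plus a paired perfusion-style label map rendered
# in its own frame (different aspect ratio, rotated and translated) so the
# registration stage has real work to do.

#' Specify a synthetic head phantom
#'
#' Defaults emulate the subtle early-infarct regime: soft tissue at 35 HU
#' with 3 HU Gaussian noise and a lesion 10 HU more hypodense than its
#' surroundings. The label map is rendered in a frame of different aspect
#' ratio under a rigid transform (rotation `theta`, translation `(tx, ty)`,
#' anisotropic scale implied by the frame shapes).
#'
#' @param n_slices Number of axial slices.
#' @param image_shape CT frame `(rows, cols)` in px.
#' @param brain_semiaxes Brain ellipse semi-axes `(row, col)` in px.
#' @param skull_thickness,skull_hu Skull ring width (px) and HU.
#' @param tissue_hu,noise_sd Soft-tissue mean HU and noise SD (HU).
#' @param lesion_side `"left"` or `"right"` (image columns).
#' @param lesion_center Lesion centre `(row, col)`, 0-based; `NULL` places it
#'   mid-hemisphere.
#' @param lesion_radius Maximal in-plane lesion radius in px.
#' @param lesion_slices Integer range of slices the lesion spans.
#' @param delta HU decrease inside the lesion (contrast).
#' @param core_fraction Fraction of the lesion radius labelled infarct core;
#'   the remaining annulus is labelled hypoperfused.
#' @param label_shape Label-map frame `(rows, cols)`; a different aspect
#'   ratio than `image_shape` exercises the registration scale handling.
#' @param theta,tx,ty Ground-truth rigid misalignment of the label frame
#'   (degrees / px, label frame into CT frame).
#' @param seed Integer seed; fully determines the phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_slices = 5, image_shape = c(96, 96),
                         brain_semiaxes = c(38, 30), skull_thickness = 3,
                         skull_hu = 1000, tissue_hu = 35, noise_sd = 3,
                         lesion_side = c("left", "right"),
                         lesion_center = NULL, lesion_radius = 11,
                         lesion_slices = NULL, delta = 10,
                         core_fraction = 0.6, label_shape = c(96, 80),
                         theta = 0, tx = 0, ty = 0, seed = 1L) {
  lesion_side <- match.arg(lesion_side)
  if (is.null(lesion_slices)) lesion_slices <- c(1L, n_slices)
  cc <- (image_shape[2] - 1) / 2
  if (is.null(lesion_center)) {
    off <- brain_semiaxes[2] / 2
    lesion_center <- c((image_shape[1] - 1) / 2,
                       if (lesion_side == "left") cc - off else cc + off)
  }
  spec <- list(n_slices = as.integer(n_slices), image_shape = image_shape,
               brain_semiaxes = brain_semiaxes,
               skull_thickness = skull_thickness, skull_hu = skull_hu,
               tissue_hu = tissue_hu, noise_sd = noise_sd,
               lesion_side = lesion_side, lesion_center = lesion_center,
               lesion_radius = lesion_radius,
               lesion_slices = as.integer(lesion_slices), delta = delta,
               core_fraction = core_fraction, label_shape = label_shape,
               theta = theta, tx = tx, ty = ty, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$delta <= 0) stop_parameter("lesion contrast delta must be > 0")
  cr <- (spec$image_shape[1] - 1) / 2
  cc <- (spec$image_shape[2] - 1) / 2
  lc <- spec$lesion_center
  r <- spec$lesion_radius
  # lesion inside the brain ellipse (with its radius as margin)
  e <- ((lc[1] - cr) / (spec$brain_semiaxes[1] - r))^2 +
       ((lc[2] - cc) / (spec$brain_semiaxes[2] - r))^2
  if (!is.finite(e) || e > 1)
    stop_parameter("lesion extends outside the brain ellipse")
  on_left <- lc[2] + r <= cc
  on_right <- lc[2] - r >= cc
  if (spec$lesion_side == "left" && !on_left)
    stop_parameter("lesion crosses the midline (side = left)")
  if (spec$lesion_side == "right" && !on_right)
    stop_parameter("lesion crosses the midline (side = right)")
  invisible(spec)
}

# per-slice lesion radius: spherical-cap profile, contiguous across the
# stated slice range, zero outside
lesion_radius_profile <- function(spec) {
  ks <- seq_len(spec$n_slices)
  lo <- spec$lesion_slices[1]; hi <- spec$lesion_slices[2]
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2 + 0.5
  r <- spec$lesion_radius * sqrt(pmax(0, 1 - ((ks - mid) / half)^2))
  r[ks < lo | ks > hi] <- 0
  r
}

#' Generate a synthetic phantom case
#'
#' @param spec A [phantom_spec].
#' @return List with `ct` ([ct_volume]), `labels` ([label_map] in the
#'   misaligned label frame, classes 0/1/2 = core/3 = hypoperfused),
#'   `transform` (ground-truth [rigid_transform] label frame -> CT frame),
#'   `truth` (3-D 0/1 array: lesion mask in the CT frame), and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  a <- spec$brain_semiaxes[1]; b <- spec$brain_semiaxes[2]
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  e_in <- ((rows - cr) / a)^2 + ((cols - cc) / b)^2
  e_out <- ((rows - cr) / (a + spec$skull_thickness))^2 +
           ((cols - cc) / (b + spec$skull_thickness))^2
  brain <- e_in <= 1
  ring <- !brain & e_out <= 1
  rad <- lesion_radius_profile(spec)
  ct <- array(-1000, c(H, W, spec$n_slices))
  truth <- array(0L, c(H, W, spec$n_slices))
  for (k in seq_len(spec$n_slices)) {
    sl <- matrix(-1000, H, W)
    sl[ring] <- spec$skull_hu
    noise <- matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    sl[brain] <- spec$tissue_hu + noise[brain]
    if (rad[k] > 0) {
      les <- brain &
        (rows - spec$lesion_center[1])^2 +
        (cols - spec$lesion_center[2])^2 <= rad[k]^2
      sl[les] <- sl[les] - spec$delta
      truth[, , k] <- as_imat(les)
    }
    ct[, , k] <- sl
  }
  # label map in its own frame, under the ground-truth transform
  Hl <- spec$label_shape[1]; Wl <- spec$label_shape[2]
  tf <- rigid_transform(theta = spec$theta, tx = spec$tx, ty = spec$ty,
                        scale = c(H / Hl, W / Wl),
                        center_moving = c((Hl - 1) / 2, (Wl - 1) / 2),
                        center_fixed = c(cr, cc))
  lrows <- matrix(0:(Hl - 1), Hl, Wl)
  lcols <- matrix(0:(Wl - 1), Hl, Wl, byrow = TRUE)
  q <- apply_rigid(tf, cbind(as.vector(lrows), as.vector(lcols)))
  qin <- ((q[, 1] - cr) / a)^2 + ((q[, 2] - cc) / b)^2 <= 1
  labs <- array(0L, c(Hl, Wl, spec$n_slices))
  for (k in seq_len(spec$n_slices)) {
    lk <- integer(Hl * Wl)
    lk[qin] <- 1L
    if (rad[k] > 0) {
      d2 <- (q[, 1] - spec$lesion_center[1])^2 +
            (q[, 2] - spec$lesion_center[2])^2
      lk[qin & d2 <= rad[k]^2] <- 3L
      lk[qin & d2 <= (spec$core_fraction * rad[k])^2] <- 2L
    }
    labs[, , k] <- matrix(lk, Hl, Wl)
  }
  list(ct = ct_volume(ct, patient_id = sprintf("phantom-%d", spec$seed)),
       labels = label_map(labs),
       transform = tf,
       truth = truth,
       spec = spec)
}

#' Generate a balanced phantom dataset
#'
#' Case-level parameters (lesion side, centre, radius, misalignment) are
#' drawn from per-case seeds derived from `master_seed`; lesion sides are
#' balanced (alternating) across cases. Difficulty sets the lesion contrast:
#' easy 20 HU, medium 10 HU, hard 5 HU.
#'
#' @param n_cases Number of cases (>= 1).
#' @param difficulty `"easy"`, `"medium"`, or `"hard"`.
#' @param master_seed Integer master seed.
#' @param n_slices,image_shape Passed to [phantom_spec()].
#' @return List with `cases` (list of [generate_phantom()] outputs) and
#'   `manifest` (list of the specs; regenerating from the manifest
#'   reproduces the dataset bit for bit).
#' @export
generate_dataset <- function(n_cases, difficulty = c("medium", "easy", "hard"),
                             master_seed = 1L, n_slices = 5,
                             image_shape = c(96, 96)) {
  if (n_cases < 1) stop_parameter("n_cases must be >= 1")
  difficulty <- match.arg(difficulty)
  delta <- c(easy = 20, medium = 10, hard = 5)[[difficulty]]
  specs <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    seed_i <- derive_seed(master_seed, i)
    set.seed(seed_i)
    side <- if (i %% 2 == 1) "left" else "right"
    cr <- (image_shape[1] - 1) / 2
    cc <- (image_shape[2] - 1) / 2
    radius <- runif(1, 8, 12)
    # lesion centre uniform in the admissible band: clear of the midline and
    # inside the brain ellipse with the lesion radius as margin
    col_off <- runif(1, radius + 2, 16)
    max_row <- (38 - radius) * sqrt(1 - (col_off / (30 - radius))^2)
    row_off <- runif(1, -0.8, 0.8) * max_row
    center <- c(cr + row_off, if (side == "left") cc - col_off
                              else cc + col_off)
    lo <- sample(1:2, 1)
    hi <- n_slices - sample(0:1, 1)
    specs[[i]] <- phantom_spec(
      n_slices = n_slices, image_shape = image_shape,
      lesion_side = side, lesion_center = center, lesion_radius = radius,
      lesion_slices = c(lo, hi), delta = delta,
      theta = runif(1, -10, 10), tx = runif(1, -10, 10),
      ty = runif(1, -10, 10), seed = derive_seed(master_seed, 1000L + i))
  }
  cases <- lapply(specs, generate_phantom)
  list(cases = cases, manifest = specs)
}
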