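# Reading, writing and display windowing of CT volumes and label maps.
#
# Internal array convention: a volume is a 3-D array indexed [row, col, slice],
# 1-based as usual in R, with slices ascending along the scan axis. "Left" and
# "right" always refer to image columns, not anatomical sides.

HU_MIN <- -1024
HU_MAX <- 3071

#' Construct a CT volume
#'
#' A `ct_volume` holds an ordered stack of axial slices in Hounsfield Units
#' (HU) together with its pixel geometry.
#'
#' @param slices 3-D numeric array `[row, col, slice]` in HU, slices ascending
#'   along the scan axis.
#' @param pixel_spacing Numeric length-2, mm per pixel as `(row, col)`.
#' @param slice_thickness Slice thickness in mm.
#' @param patient_id Opaque identifier string.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(slices, pixel_spacing = c(1, 1), slice_thickness = 5,
                      patient_id = "anonymous") {
  if (length(dim(slices)) == 2L) dim(slices) <- c(dim(slices), 1L)
  if (length(dim(slices)) != 3L)
    stop_geometry("slices must be a 3-D array [row, col, slice]")
  rng <- range(slices)
  if (rng[1] < HU_MIN || rng[2] > HU_MAX)
    stop_parameter(sprintf("HU values outside [%d, %d]: range %.1f..%.1f",
                           HU_MIN, HU_MAX, rng[1], rng[2]))
  structure(list(slices = slices,
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_thickness = as.numeric(slice_thickness),
                 patient_id = as.character(patient_id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<ct_volume> %d slices of %dx%d px, spacing %.2fx%.2f mm, patient %s\n",
              d[3], d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2],
              x$patient_id))
  invisible(x)
}

#' Construct a label map
#'
#' Integer per-pixel class map. Class codes: 0 = background, 1 = normal
#' tissue, 2 = infarct core, 3 = hypoperfused (at-risk) tissue. After
#' collapsing for training only classes 0..2 remain, with 2 = infarct.
#'
#' @param labels 3-D (or 2-D) integer array of class codes.
#' @param classes Integer vector of admissible codes.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, classes = 0:3) {
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  labels <- as_imat(labels)
  bad <- setdiff(unique(as.vector(labels)), classes)
  if (length(bad))
    stop_parameter(paste("unknown label classes:", paste(bad, collapse = ", ")))
  structure(list(labels = labels, classes = as.integer(classes)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d slices of %dx%d px, classes {%s}\n",
              d[3], d[1], d[2], paste(sort(unique(as.vector(x$labels))),
                                      collapse = ",")))
  invisible(x)
}

#' Map HU values onto display grey levels
#'
#' Affine clip-and-scale windowing. The default (40, 100) window is the
#' "stroke window" used to read subtle grey/white hypodensity. Values at or
#' below `low` map to 0, at or above `high` to 255; in between the map is
#' affine with round-half-to-even rounding, so e.g. HU 70 under (40, 100)
#' gives 255 * 30/60 = 127.5, rounded to 128.
#'
#' @param slice 2-D numeric matrix in HU.
#' @param low,high Window bounds in HU, `low < high`.
#' @return A `windowed_slice`: list with integer matrix `gray` in 0..255 and
#'   the `window` used.
#' @export
window_hu <- function(slice, low = 40, high = 100) {
  if (low >= high) stop_parameter("window requires low < high")
  g <- 255 * (slice - low) / (high - low)
  g <- round(g)                      # round-half-to-even
  g[g < 0] <- 0
  g[g > 255] <- 255
  structure(list(gray = as_imat(g), window = c(low, high)),
            class = "windowed_slice")
}

#' Read a CT volume
#'
#' Supported formats: `"nifti"` (a `.nii`/`.nii.gz` file, values already in
#' HU), `"dicom_dir"` (a directory of single-frame DICOM files, one per
#' slice; the rescale slope/intercept is applied to convert stored values to
#' HU), and `"rds"` (the package's own serialized form, used for lossless
#' intermediate storage).
#'
#' @param path File (nifti/rds) or directory (dicom_dir).
#' @param format One of `"nifti"`, `"dicom_dir"`, `"rds"`.
#' @return A [ct_volume].
#' @export
read_volume <- function(path, format = c("nifti", "dicom_dir", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_format(paste("no such file or directory:", path))
  switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- array(as.numeric(img), dim = dim(img))
      if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
      pd <- RNifti::pixdim(img)
      ct_volume(arr, pixel_spacing = pd[1:2],
                slice_thickness = if (length(pd) >= 3) pd[3] else 5)
    },
    dicom_dir = read_dicom_series(path),
    rds = {
      obj <- readRDS(path)
      if (!inherits(obj, "ct_volume"))
        stop_format(paste("not a serialized ct_volume:", path))
      obj
    })
}

#' Read a label map
#'
#' @param path File path.
#' @param format `"nifti"` or `"rds"`.
#' @return A [label_map].
#' @export
read_label_map <- function(path, format = c("nifti", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- array(as.numeric(img), dim = dim(img))
      label_map(round(arr))
    },
    rds = {
      obj <- readRDS(path)
      if (!inherits(obj, "label_map"))
        stop_format(paste("not a serialized label_map:", path))
      obj
    })
}

#' Write a volume, label map or probability map
#'
#' Masks and label maps are persisted losslessly as 16-bit integers;
#' probability maps and HU volumes at full double precision.
#'
#' @param x A [ct_volume], [label_map], or numeric array (probability map).
#' @param path Output file path; the parent directory must exist.
#' @param format `"nifti"` or `"rds"`.
#' @export
write_outputs <- function(x, path, format = c("nifti", "rds")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop_format(paste("parent directory does not exist:", dirname(path)))
  if (format == "rds") {
    saveRDS(x, path)
    return(invisible(path))
  }
  if (inherits(x, "ct_volume")) {
    img <- RNifti::asNifti(x$slices)
    RNifti::pixdim(img) <- c(x$pixel_spacing, x$slice_thickness)
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (inherits(x, "label_map")) {
    RNifti::writeNifti(RNifti::asNifti(x$labels), path, datatype = "int16")
  } else if (is.array(x) || is.matrix(x)) {
    arr <- x
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "double")
  } else {
    stop_usage("unsupported object type for write_outputs")
  }
  invisible(path)
}
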