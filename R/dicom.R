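# Minimal read-only DICOM support for axial CT series.
#
# No installed R package reads DICOM, so a small parser is included. It
# covers what CT slice files need: little-endian transfer syntaxes (implicit
# and explicit VR), single-frame 16-bit pixel data, rescale slope/intercept,
# pixel spacing and slice ordering. Sequences with undefined length and
# compressed transfer syntaxes are rejected with a format error.

.dicom_short_vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD",
                      "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM",
                      "UI", "UL", "US")
.dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_uint16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}

read_uint32 <- function(raw, off) {
  as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
    65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
}

# Parse one DICOM file into the handful of elements the reader needs.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  off <- 0L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") off <- 132L
  els <- list()
  n <- length(raw)
  while (off + 8 <= n) {
    group <- read_uint16(raw, off)
    elem <- read_uint16(raw, off + 2L)
    vb <- as.integer(raw[(off + 5L):(off + 6L)])
    vr <- if (all(vb >= 65L & vb <= 90L))
      rawToChar(raw[(off + 5L):(off + 6L)]) else ""
    explicit <- vr %in% c(.dicom_short_vrs, .dicom_long_vrs)
    if (explicit) {
      if (vr %in% .dicom_long_vrs) {
        len <- read_uint32(raw, off + 8L)
        voff <- off + 12L
      } else {
        len <- read_uint16(raw, off + 6L)
        voff <- off + 8L
      }
    } else {
      vr <- NA_character_
      len <- read_uint32(raw, off + 4L)
      voff <- off + 8L
    }
    if (len >= 4294967295)
      stop_format(paste("undefined-length element unsupported in", path))
    if (voff + len > n)
      stop_format(paste("truncated DICOM element in", path))
    tag <- sprintf("%04x,%04x", group, elem)
    els[[tag]] <- list(vr = vr, value = raw[seq_len(len) + voff])
    off <- voff + as.integer(len)
    if (tag == "7fe0,0010") break  # pixel data is last element we need
  }
  els
}

dicom_string <- function(els, tag) {
  e <- els[[tag]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$value))
}

dicom_numeric <- function(els, tag) {
  s <- dicom_string(els, tag)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_uint16_value <- function(els, tag) {
  e <- els[[tag]]
  if (is.null(e)) return(NULL)
  read_uint16(e$value, 0L)
}

# Read one slice file: returns HU matrix plus geometry fields.
read_dicom_slice <- function(path) {
  els <- parse_dicom_file(path)
  rows <- dicom_uint16_value(els, "0028,0010")
  cols <- dicom_uint16_value(els, "0028,0011")
  px <- els[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop_format(paste("not a DICOM image file:", path))
  bits <- dicom_uint16_value(els, "0028,0100") %||% 16L
  if (bits != 16L)
    stop_format(paste("only 16-bit pixel data supported:", path))
  signed <- (dicom_uint16_value(els, "0028,0103") %||% 0L) == 1L
  stored <- readBin(px$value, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  if (length(stored) < rows * cols)
    stop_format(paste("pixel data shorter than Rows*Columns in", path))
  slope <- (dicom_numeric(els, "0028,1053") %||% 1)[1]
  intercept <- (dicom_numeric(els, "0028,1052") %||% 0)[1]
  hu <- matrix(stored * slope + intercept, nrow = rows, ncol = cols,
               byrow = TRUE)  # DICOM pixel data is row-major
  ipp <- dicom_numeric(els, "0020,0032")
  list(hu = hu,
       z = if (!is.null(ipp) && length(ipp) >= 3) ipp[3] else NA_real_,
       instance = (dicom_numeric(els, "0020,0013") %||% NA_real_)[1],
       spacing = dicom_numeric(els, "0028,0030") %||% c(1, 1),
       thickness = (dicom_numeric(els, "0018,0050") %||% 5)[1],
       patient = dicom_string(els, "0010,0020") %||% "anonymous")
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    stop_format(paste("no image files in directory:", dir))
  slices <- lapply(files, read_dicom_slice)
  shp <- vapply(slices, function(s) dim(s$hu), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop_geometry("inconsistent slice shapes across DICOM series")
  z <- vapply(slices, function(s) s$z, numeric(1))
  ord <- if (!anyNA(z)) order(z) else
    order(vapply(slices, function(s) s$instance, numeric(1)))
  slices <- slices[ord]
  arr <- array(0, dim = c(shp[1, 1], shp[2, 1], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$hu
  ct_volume(arr, pixel_spacing = slices[[1]]$spacing,
            slice_thickness = slices[[1]]$thickness,
            patient_id = slices[[1]]$patient)
}

# Write a minimal valid explicit-VR little-endian DICOM slice. Used to build
# test fixtures and round-trip checks; not a clinical-grade writer.
write_minimal_dicom <- function(hu_or_stored, path, slope = 1,
                                intercept = -1024, z = 0, instance = 1,
                                spacing = c(1, 1), stored_values = NULL) {
  stored <- if (!is.null(stored_values)) stored_values else
    round((hu_or_stored - intercept) / slope)
  stored <- as_imat(as.matrix(stored))
  rows <- nrow(stored); cols <- ncol(stored)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  put_short <- function(group, elem, vr, value_raw) {
    writeBin(as.integer(c(group, elem)), con, size = 2L, endian = "little")
    writeChar(vr, con, eos = NULL)
    writeBin(length(value_raw), con, size = 2L, endian = "little")
    writeBin(value_raw, con)
  }
  str_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
    r
  }
  us_raw <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                                 endian = "little")
  put_short(0x0010, 0x0020, "LO", str_raw("phantom"))
  put_short(0x0018, 0x0050, "DS", str_raw("5"))
  put_short(0x0020, 0x0013, "IS", str_raw(as.character(instance)))
  put_short(0x0020, 0x0032, "DS",
            str_raw(sprintf("0\\0\\%g", z)))
  put_short(0x0028, 0x0010, "US", us_raw(rows))
  put_short(0x0028, 0x0011, "US", us_raw(cols))
  put_short(0x0028, 0x0030, "DS",
            str_raw(sprintf("%g\\%g", spacing[1], spacing[2])))
  put_short(0x0028, 0x0100, "US", us_raw(16L))
  put_short(0x0028, 0x0103, "US", us_raw(1L))  # signed stored values
  put_short(0x0028, 0x1052, "DS", str_raw(as.character(intercept)))
  put_short(0x0028, 0x1053, "DS", str_raw(as.character(slope)))
  px <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
  writeBin(as.integer(c(0x7fe0, 0x0010)), con, size = 2L, endian = "little")
  writeChar("OW", con, eos = NULL)
  writeBin(as.integer(0), con, size = 2L, endian = "little")
  writeBin(length(px), con, size = 4L, endian = "little")
  writeBin(px, con)
  invisible(path)
}
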