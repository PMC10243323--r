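# Minimal DICOM support: single-frame, uncompressed, explicit-VR
# little-endian files only — enough to round-trip the synthetic series the
# test surface uses and to pull Rows/Columns/PixelSpacing/PixelData from
# scanner exports of that flavor. Sequences, compressed transfer syntaxes
# and multi-frame objects are out of scope.

DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read a single-frame DICOM file
#'
#' Supports uncompressed explicit-VR little-endian files. Rescale slope and
#' intercept are applied when present (CT Hounsfield units).
#'
#' @param path DICOM file path.
#' @return A list with `pixels` (numeric matrix, row = DICOM row),
#'   `spacing_mm` (row, col), `slice_thickness_mm`, `instance_number`,
#'   `modality`.
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) stop("read_dicom_slice: no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 160 || rawToChar(raw[129:132]) != "DICM")
    stop("read_dicom_slice: not a DICOM part-10 file: ", path)
  pos <- 133L
  meta <- list(rows = NA, cols = NA, spacing = c(NA, NA), thick = NA,
               inst = NA, modality = "MR", bits = 16L, signed = FALSE,
               slope = 1, intercept = 0, pixeldata = NULL)
  n <- length(raw)
  while (pos + 8L <= n + 1L) {
    grp <- readBin(raw[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
                   endian = "little")
    ele <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2,
                   signed = FALSE, endian = "little")
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% DICOM_LONG_VRS) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      hdr <- 12L
    } else {
      len <- readBin(raw[(pos + 6):(pos + 7)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      hdr <- 8L
    }
    if (len < 0 || pos + hdr + len > n + 1L)
      stop("read_dicom_slice: corrupt element at byte ", pos, " in ", path)
    val <- raw[(pos + hdr):(pos + hdr + len - 1L)]
    if (len == 0L) val <- raw(0)
    tag <- sprintf("%04x%04x", grp, ele)
    if (tag == "00280010") meta$rows <- u16(val)
    else if (tag == "00280011") meta$cols <- u16(val)
    else if (tag == "00280030") meta$spacing <- ds_values(val)
    else if (tag == "00180050") meta$thick <- ds_values(val)[1]
    else if (tag == "00200013") meta$inst <- as.integer(trimws(rawToChar(val)))
    else if (tag == "00080060") meta$modality <- trimws(rawToChar(val))
    else if (tag == "00280100") meta$bits <- u16(val)
    else if (tag == "00280103") meta$signed <- u16(val) == 1L
    else if (tag == "00281052") meta$intercept <- ds_values(val)[1]
    else if (tag == "00281053") meta$slope <- ds_values(val)[1]
    else if (tag == "7fe00010") meta$pixeldata <- val
    pos <- pos + hdr + len
    if (!is.null(meta$pixeldata)) break
  }
  if (is.null(meta$pixeldata) || is.na(meta$rows) || is.na(meta$cols))
    stop("read_dicom_slice: missing Rows/Columns/PixelData in ", path)
  if (meta$bits != 16L)
    stop("read_dicom_slice: only 16-bit pixel data supported")
  vals <- readBin(meta$pixeldata, "integer", n = meta$rows * meta$cols,
                  size = 2, signed = meta$signed, endian = "little")
  if (!meta$signed) vals <- vals %% 65536L  # readBin size-2 unsigned quirk
  px <- matrix(vals, nrow = meta$rows, ncol = meta$cols, byrow = TRUE)
  px <- px * meta$slope + meta$intercept
  list(pixels = px, spacing_mm = as.numeric(meta$spacing),
       slice_thickness_mm = meta$thick, instance_number = meta$inst,
       modality = meta$modality)
}

u16 <- function(val) {
  readBin(val[1:2], "integer", size = 2, signed = FALSE, endian = "little")
}

ds_values <- function(val) {
  as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]])
}

#' Write a single-frame DICOM file
#'
#' Produces a minimal explicit-VR little-endian part-10 file carrying the
#' tags the reader consumes. Pixel intensities are rounded to integers;
#' signed storage with a rescale intercept is used for CT so Hounsfield
#' units round-trip.
#'
#' @param pixels numeric matrix.
#' @param path output path.
#' @param spacing_mm (row, col) pixel spacing in mm.
#' @param slice_thickness_mm slice thickness.
#' @param instance_number slice index within the series.
#' @param modality `"MR"` or `"CT"`.
#' @return Invisibly, `path`.
#' @export
write_dicom_slice <- function(pixels, path, spacing_mm = c(1, 1),
                              slice_thickness_mm = 1, instance_number = 1,
                              modality = "MR") {
  pixels <- round(as.matrix(pixels))
  signed <- any(pixels < 0)
  if (signed && (any(pixels < -32768) || any(pixels > 32767)))
    stop("write_dicom_slice: signed pixel values out of 16-bit range")
  if (!signed && any(pixels > 65535))
    stop("write_dicom_slice: pixel values out of 16-bit range")
  el <- function(grp, ele, vr, val) {
    if (is.character(val)) {
      v <- charToRaw(val)
      if (length(v) %% 2 == 1) v <- c(v, charToRaw(" "))
    } else v <- val
    tag <- writeBin(as.integer(c(grp, ele)), raw(), size = 2,
                    endian = "little")
    if (vr %in% DICOM_LONG_VRS)
      c(tag, charToRaw(vr), as.raw(c(0, 0)),
        writeBin(length(v), raw(), size = 4, endian = "little"), v)
    else
      c(tag, charToRaw(vr),
        writeBin(length(v), raw(), size = 2, endian = "little"), v)
  }
  # file meta group (group 0002 is implicitly explicit-VR little endian)
  tsuid <- "1.2.840.10008.1.2.1"  # explicit VR little endian
  meta <- c(el(2L, 0x0010L, "UI", tsuid))
  meta_grouplen <- el(2L, 0L, "UL",
                      writeBin(length(meta), raw(), size = 4,
                               endian = "little"))
  pdraw <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")
  body <- c(
    el(0x0008L, 0x0060L, "CS", modality),
    el(0x0018L, 0x0050L, "DS", format(slice_thickness_mm)),
    el(0x0020L, 0x0013L, "IS", format(as.integer(instance_number))),
    el(0x0028L, 0x0010L, "US", writeBin(as.integer(nrow(pixels)), raw(),
                                        size = 2, endian = "little")),
    el(0x0028L, 0x0011L, "US", writeBin(as.integer(ncol(pixels)), raw(),
                                        size = 2, endian = "little")),
    el(0x0028L, 0x0030L, "DS", paste(format(spacing_mm[1]),
                                     format(spacing_mm[2]), sep = "\\")),
    el(0x0028L, 0x0100L, "US", writeBin(16L, raw(), size = 2,
                                        endian = "little")),
    el(0x0028L, 0x0103L, "US", writeBin(as.integer(signed), raw(), size = 2,
                                        endian = "little")),
    el(0x7fe0L, 0x0010L, "OW", pdraw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta_grouplen, meta, body), con)
  invisible(path)
}

read_dicom_dir <- function(path, as, plane_label, frame_rate_fps, modality) {
  fs <- list.files(path, full.names = TRUE)
  fs <- fs[!dir.exists(fs)]
  if (length(fs) == 0) stop("read_image_series: empty directory: ", path)
  slices <- lapply(fs, read_dicom_slice)
  ord <- order(vapply(slices, function(s)
    ifelse(is.na(s$instance_number), 0L, s$instance_number), integer(1)))
  slices <- slices[ord]
  sp <- slices[[1]]$spacing_mm
  if (as == "cine") {
    frames <- lapply(slices, function(s)
      planar_image(s$pixels, sp, plane_label))
    return(cine_sequence(frames, frame_rate_fps))
  }
  d <- dim(slices[[1]]$pixels)
  if (!all(vapply(slices, function(s) identical(dim(s$pixels), d),
                  logical(1))))
    stop("read_image_series: inconsistent DICOM slice shapes in ", path)
  # stack: DICOM row = AP (y), col = lateral (x), slices along SI (z)
  vox <- array(0, c(d[2], d[1], length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- t(slices[[k]]$pixels)
  thick <- slices[[1]]$slice_thickness_mm
  if (is.na(thick)) thick <- sp[1]
  mod <- if (slices[[1]]$modality %in% c("MR", "CT")) slices[[1]]$modality
         else modality
  volume_image(vox, c(sp[2], sp[1], thick), mod)
}
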