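# Domain containers shared by every module. All are light S3 wrappers around
# base matrices/arrays so that EBImage and the compiled samplers can consume
# the pixel data directly.
#
# Coordinate conventions (package-wide):
#  * Pixel indices are 1-based (R convention); physical position of pixel
#    [r, c] is x = (c-1)*spacing_col mm, y = (r-1)*spacing_row mm.
#  * Volumes are arrays [i, j, k] = (lateral L->R, anterior->posterior,
#    inferior->superior); physical mm analogous.
#  * In-plane rotation is counterclockwise-positive when viewed along the
#    +normal of the plane in patient coordinates.

#' Planar MR image
#'
#' A single 2D cine or phantom frame: a numeric pixel matrix plus its pixel
#' spacing and the anatomical plane it samples.
#'
#' @param pixels numeric matrix of intensities (finite).
#' @param spacing_mm length-2 positive numeric, (row, col) pixel size in mm.
#' @param plane_label one of `"axial"`, `"sagittal"`, `"coronal"`.
#' @return A `planar_image` object.
#' @export
planar_image <- function(pixels, spacing_mm = c(1.3, 1.3),
                         plane_label = "axial") {
  pixels <- as.matrix(pixels)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  stopifnot(is.numeric(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  if (!all(is.finite(pixels))) stop("planar_image: intensities must be finite")
  if (!(length(spacing_mm) == 2 && all(spacing_mm > 0)))
    stop("planar_image: spacing_mm must be two positive values")
  plane_label <- match.arg(plane_label, c("axial", "sagittal", "coronal"))
  structure(list(pixels = pixels, spacing_mm = as.numeric(spacing_mm),
                 plane_label = plane_label),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %d x %d px, %.3g x %.3g mm, plane %s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm[1], x$spacing_mm[2],
              x$plane_label))
  invisible(x)
}

#' @export
dim.planar_image <- function(x) dim(x$pixels)

#' Planar cine sequence
#'
#' A time-ordered stack of same-shape [planar_image] frames for one
#' anatomical plane, with the acquisition frame rate and per-frame
#' timestamps.
#'
#' @param frames list of [planar_image] objects sharing shape and spacing.
#' @param frame_rate_fps frames per second (> 0). Three-plane interleaved
#'   brain-coil acquisition runs at 0.5 fps; two planes at 0.9 fps; a single
#'   plane at 1.8--2 fps.
#' @param timestamps optional nondecreasing vector of seconds, defaults to
#'   `(seq_along(frames) - 1) / frame_rate_fps`.
#' @return A `cine_sequence` object.
#' @export
cine_sequence <- function(frames, frame_rate_fps = 0.5, timestamps = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  if (!all(vapply(frames, inherits, logical(1), "planar_image")))
    stop("cine_sequence: frames must be planar_image objects")
  d1 <- dim(frames[[1]]$pixels)
  s1 <- frames[[1]]$spacing_mm
  same <- vapply(frames, function(f)
    identical(dim(f$pixels), d1) && isTRUE(all.equal(f$spacing_mm, s1)),
    logical(1))
  if (!all(same)) stop("cine_sequence: frames differ in shape or spacing")
  if (!(is.numeric(frame_rate_fps) && frame_rate_fps > 0))
    stop("cine_sequence: frame_rate_fps must be > 0")
  if (is.null(timestamps))
    timestamps <- (seq_along(frames) - 1) / frame_rate_fps
  if (length(timestamps) != length(frames) || is.unsorted(timestamps))
    stop("cine_sequence: timestamps must be nondecreasing, one per frame")
  structure(list(frames = frames, frame_rate_fps = frame_rate_fps,
                 timestamps = as.numeric(timestamps),
                 plane_label = frames[[1]]$plane_label),
            class = "cine_sequence")
}

#' @export
length.cine_sequence <- function(x) length(x$frames)

#' @export
print.cine_sequence <- function(x, ...) {
  cat(sprintf("<cine_sequence> %d frames (%s), %.2f fps, %d x %d px\n",
              length(x$frames), x$plane_label, x$frame_rate_fps,
              nrow(x$frames[[1]]$pixels), ncol(x$frames[[1]]$pixels)))
  invisible(x)
}

#' Volumetric image
#'
#' A 3D MR or CT volume on the patient axes x = lateral (L to R),
#' y = anterior to posterior, z = inferior to superior.
#'
#' @param voxels numeric 3D array `[x, y, z]`.
#' @param spacing_mm length-3 positive numeric (x, y, z) voxel size in mm.
#' @param modality `"MR"` or `"CT"`.
#' @return A `volume_image` object.
#' @export
volume_image <- function(voxels, spacing_mm = c(1, 1, 1), modality = "MR") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (!all(is.finite(voxels))) stop("volume_image: voxels must be finite")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (!(length(spacing_mm) == 3 && all(spacing_mm > 0)))
    stop("volume_image: spacing_mm must be three positive values")
  modality <- match.arg(modality, c("MR", "CT"))
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 modality = modality),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %s %d x %d x %d vox, %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3]))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

#' Binary region-of-interest mask
#'
#' A logical grid congruent with its host image (2D or 3D).
#'
#' @param mask logical matrix or array.
#' @param label short text label for reports.
#' @return A `mask_roi` object.
#' @export
mask_roi <- function(mask, label = "") {
  if (is.numeric(mask)) mask <- mask != 0
  stopifnot(is.logical(mask), is.matrix(mask) || is.array(mask))
  structure(list(mask = mask, label = as.character(label)),
            class = "mask_roi")
}

#' @export
print.mask_roi <- function(x, ...) {
  cat(sprintf("<mask_roi> '%s': %d of %d elements\n", x$label,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

# Internal: check that a mask matches a host image and is non-empty.
check_roi <- function(roi, host = NULL, require_nonempty = TRUE) {
  stopifnot(inherits(roi, "mask_roi"))
  if (!is.null(host)) {
    hd <- if (inherits(host, "planar_image")) dim(host$pixels)
          else if (inherits(host, "volume_image")) dim(host$voxels)
          else dim(host)
    if (!identical(dim(roi$mask), hd))
      stop("mask_roi shape does not match the host image")
  }
  if (require_nonempty && !any(roi$mask))
    stop("mask_roi is empty but a non-empty region is required")
  invisible(TRUE)
}

#' In-plane rigid transform
#'
#' Two translations (mm, along image x = columns and y = rows) plus one
#' rotation (degrees, counterclockwise positive) about `center_mm`.
#'
#' @param dx_mm,dy_mm translations in mm.
#' @param theta_deg rotation in degrees, wrapped to (-180, 180].
#' @param center_mm rotation center `(x, y)` in mm (image coordinates).
#' @return A `rigid2d` object.
#' @export
rigid2d <- function(dx_mm = 0, dy_mm = 0, theta_deg = 0, center_mm = c(0, 0)) {
  v <- c(dx_mm, dy_mm, theta_deg, center_mm)
  if (!all(is.finite(v))) stop("rigid2d: parameters must be finite")
  theta_deg <- ((theta_deg + 180) %% 360) - 180
  if (theta_deg == -180) theta_deg <- 180
  structure(list(dx_mm = dx_mm, dy_mm = dy_mm, theta_deg = theta_deg,
                 center_mm = as.numeric(center_mm)),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d> dx %.3f mm, dy %.3f mm, theta %.3f deg\n",
              x$dx_mm, x$dy_mm, x$theta_deg))
  invisible(x)
}

#' Six degree-of-freedom rigid transform
#'
#' Translations along the patient axes (lateral, AP, SI; mm) and rotations
#' roll (about AP), pitch (about lateral), yaw (about SI) in degrees,
#' applied extrinsically in the order yaw, pitch, roll.
#'
#' @param lat_mm,ap_mm,si_mm translations in mm.
#' @param roll_deg,pitch_deg,yaw_deg rotations in degrees.
#' @return A `rigid3d` object.
#' @export
rigid3d <- function(lat_mm = 0, ap_mm = 0, si_mm = 0,
                    roll_deg = 0, pitch_deg = 0, yaw_deg = 0) {
  v <- c(lat_mm, ap_mm, si_mm, roll_deg, pitch_deg, yaw_deg)
  if (!all(is.finite(v))) stop("rigid3d: parameters must be finite")
  structure(list(lat_mm = lat_mm, ap_mm = ap_mm, si_mm = si_mm,
                 roll_deg = roll_deg, pitch_deg = pitch_deg,
                 yaw_deg = yaw_deg),
            class = "rigid3d")
}

#' @export
print.rigid3d <- function(x, ...) {
  cat(sprintf(
    "<rigid3d> lat %.2f, AP %.2f, SI %.2f mm; roll %.2f, pitch %.2f, yaw %.2f deg\n",
    x$lat_mm, x$ap_mm, x$si_mm, x$roll_deg, x$pitch_deg, x$yaw_deg))
  invisible(x)
}

# Internal: 6-vector view of a rigid3d (mm, mm, mm, deg, deg, deg).
as_vector_rigid3d <- function(tf) {
  c(tf$lat_mm, tf$ap_mm, tf$si_mm, tf$roll_deg, tf$pitch_deg, tf$yaw_deg)
}
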