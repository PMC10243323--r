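# Readers/writers for the standard formats used by the toolkit. All
# downstream modules consume only the domain types built here.

#' Read an image series from disk
#'
#' Dispatches on format: a NIfTI file becomes a [volume_image]; a directory
#' of PNG/TIFF frames (sorted by file name) becomes a [cine_sequence]; a
#' directory of single-frame DICOM files becomes a [volume_image] (or a
#' [cine_sequence] when `as = "cine"`), with pixel spacing taken from the
#' DICOM metadata.
#'
#' @param path file (NIfTI) or directory (PNG/TIFF/DICOM series).
#' @param format one of `"auto"`, `"nifti"`, `"png"`, `"tiff"`, `"dicom"`.
#' @param spacing_mm override/supply pixel spacing (required for PNG/TIFF,
#'   which carry no physical metadata).
#' @param plane_label anatomical plane for planar stacks.
#' @param frame_rate_fps frame rate for cine stacks (default 0.5, the
#'   three-plane interleaved preset).
#' @param as for DICOM directories: `"volume"` (default) or `"cine"`.
#' @param modality modality tag for volumes read from rasters.
#' @return A [volume_image] or [cine_sequence].
#' @export
read_image_series <- function(path, format = "auto", spacing_mm = NULL,
                              plane_label = "axial", frame_rate_fps = 0.5,
                              as = c("volume", "cine"), modality = "MR") {
  as <- match.arg(as)
  if (!file.exists(path)) stop("read_image_series: path does not exist: ", path)
  format <- match.arg(format, c("auto", "nifti", "png", "tiff", "dicom"))
  if (format == "auto") format <- guess_series_format(path)
  switch(format,
    nifti = read_nifti_volume(path, spacing_mm, modality),
    png = ,
    tiff = read_raster_stack(path, format, spacing_mm, plane_label,
                             frame_rate_fps),
    dicom = read_dicom_dir(path, as, plane_label, frame_rate_fps, modality)
  )
}

guess_series_format <- function(path) {
  if (dir.exists(path)) {
    fs <- list.files(path)
    if (length(fs) == 0) stop("read_image_series: empty directory: ", path)
    ext <- tolower(tools::file_ext(fs))
    if (any(ext == "png")) return("png")
    if (any(ext %in% c("tif", "tiff"))) return("tiff")
    if (any(ext %in% c("dcm", "ima")) || any(ext == "")) return("dicom")
    stop("read_image_series: cannot infer format from files in ", path)
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") return("nifti")
  if (ext == "dcm") return("dicom")
  stop("read_image_series: cannot infer format of ", path)
}

read_nifti_volume <- function(path, spacing_mm, modality) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  sp <- if (!is.null(spacing_mm)) spacing_mm else RNifti::pixdim(img)[1:3]
  volume_image(arr, sp, modality)
}

read_raster_stack <- function(path, format, spacing_mm, plane_label,
                              frame_rate_fps) {
  if (!dir.exists(path)) stop("read_image_series: expected a directory: ", path)
  pat <- if (format == "png") "\\.png$" else "\\.tiff?$"
  fs <- sort(list.files(path, pattern = pat, full.names = TRUE,
                        ignore.case = TRUE))
  if (length(fs) == 0) stop("read_image_series: no ", format, " files in ", path)
  if (is.null(spacing_mm))
    stop("read_image_series: spacing_mm must be supplied for raster stacks")
  reader <- if (format == "png") png::readPNG else tiff::readTIFF
  frames <- lapply(fs, function(f) {
    px <- tryCatch(reader(f), error = function(e)
      stop("read_image_series: cannot read ", f, ": ", conditionMessage(e)))
    if (length(dim(px)) == 3) px <- px[, , 1]
    planar_image(px, spacing_mm, plane_label)
  })
  d1 <- dim(frames[[1]]$pixels)
  bad <- which(!vapply(frames, function(f) identical(dim(f$pixels), d1),
                       logical(1)))
  if (length(bad))
    stop("read_image_series: inconsistent frame shape in ", fs[bad[1]])
  cine_sequence(frames, frame_rate_fps)
}

#' Write a cine sequence as a raster stack
#'
#' Intensities must lie in `[0, 65535]`. TIFF frames are stored with 16-bit
#' samples, so integer-valued pixels round-trip exactly through
#' [read_image_series()]; PNG frames are 8-bit (intensities quantized to
#' 256 levels), kept for viewers that cannot read TIFF.
#'
#' @param seq a [cine_sequence].
#' @param dir output directory (created if missing).
#' @param format `"tiff"` (lossless 16-bit, default) or `"png"` (8-bit).
#' @return Invisibly, the written file paths.
#' @export
write_cine_raster <- function(seq, dir, format = c("tiff", "png")) {
  stopifnot(inherits(seq, "cine_sequence"))
  format <- match.arg(format)
  rng <- range(vapply(seq$frames, function(f) range(f$pixels), numeric(2)))
  if (rng[1] < 0 || rng[2] > 65535)
    stop("write_cine_raster: intensities must lie in [0, 65535]")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%04d.%s", seq_along(seq$frames),
                                  if (format == "tiff") "tif" else "png"))
  for (i in seq_along(seq$frames)) {
    if (format == "tiff")
      tiff::writeTIFF(seq$frames[[i]]$pixels / 65535, paths[i],
                      bits.per.sample = 16L)
    else
      png::writePNG(seq$frames[[i]]$pixels / 65535, paths[i])
  }
  invisible(paths)
}

#' Write a volume as NIfTI
#'
#' @param vol a [volume_image].
#' @param path output `.nii` or `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_nifti_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a motion trace to CSV
#'
#' One row per frame. Planar traces carry `time_s, dx_mm, dy_mm, theta_deg,
#' score`; 6-DOF traces carry `time_s, lat_mm, ap_mm, si_mm, roll_deg,
#' pitch_deg, yaw_deg`. Values are written at 6 decimals and round-trip at
#' that precision through [read_trace()].
#'
#' @param trace a `motion_trace` or `sixdof_trace`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  if (nrow(df) == 0) stop("write_trace: trace is empty")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("write_trace: cannot write ", path)
  invisible(path)
}

#' Read a motion trace CSV written by [write_trace()]
#'
#' @param path CSV path.
#' @return A data frame with class `motion_trace` or `sixdof_trace`
#'   according to its columns.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("read_trace: no such file: ", path)
  df <- read.csv(path)
  cls <- if ("lat_mm" %in% names(df)) "sixdof_trace" else "motion_trace"
  class(df) <- c(cls, "data.frame")
  df
}

#' Load a YAML run configuration
#'
#' Unknown top-level keys are rejected so that typos in configuration files
#' surface immediately.
#'
#' @param path YAML file.
#' @param allowed character vector of permitted top-level keys.
#' @return Named list of configuration values.
#' @export
load_run_config <- function(path,
                            allowed = c("search", "contour", "crossline",
                                        "skull_band", "gating_margin_mm",
                                        "fps", "spacing_mm", "seed",
                                        "crop_margin", "inpaint_overlays",
                                        "reconcile", "plane")) {
  if (!file.exists(path)) stop("load_run_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("load_run_config: unknown keys: ", paste(unknown, collapse = ", "))
  cfg
}
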