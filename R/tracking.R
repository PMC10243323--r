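# Steps (1)-(7) wired together per frame, combination of the three
# orthogonal-plane traces into a 6-DOF head-motion trace, and the per-segment
# motion summary.

#' Track a planar cine sequence
#'
#' Runs the full pipeline: crop the system border; detect, fill and (if
#' requested) inpaint the contours on every frame; detect crossline
#' artifacts per frame; build the per-frame skull-band ROI; register every
#' frame to the first frame. The first frame's entry is the identity with
#' similarity 1.
#'
#' @param seq a [cine_sequence] with at least 2 frames.
#' @param config list overriding any of: `crop_margin`, `contour` (see
#'   [detect_contours()]), `inpaint_overlays` (logical, default `FALSE`;
#'   enable for console exports with burned-in contour graphics — the
#'   tracking/gating outline pixels are then inpainted in every frame;
#'   leave off for clean frames, where inpainting would only discard
#'   skull-edge signal), `crossline`
#'   (`list(k =, window =, axes =)`; `axes = character(0)` disables
#'   artifact exclusion), `skull_band`, `search` (see [search_config()]).
#' @return A `motion_trace` data frame: `frame`, `time_s`, `dx_mm`,
#'   `dy_mm`, `theta_deg`, `score`, `boundary_warning`; attributes
#'   `plane_label`, `center_mm`, `contours`.
#' @export
track_sequence <- function(seq, config = list()) {
  stopifnot(inherits(seq, "cine_sequence"))
  if (length(seq) < 2) stop("track_sequence: need at least 2 frames")
  cfg <- modifyList(list(crop_margin = "auto", contour = list(),
                         inpaint_overlays = FALSE,
                         crossline = list(k = 5, window = 5,
                                          axes = c("row", "col")),
                         skull_band = c(outer_mm = 2, inner_mm = 9),
                         search = search_config()), config)
  seq <- crop_system_boundary(seq, cfg$crop_margin)
  sp <- seq$frames[[1]]$spacing_mm

  cs <- detect_contours(seq$frames[[1]], cfg$contour)
  fc <- fill_contour(cs$target_outline)
  filled <- fc$filled
  center_mm <- c((fc$rotation_center[2] - 1) * sp[2],
                 (fc$rotation_center[1] - 1) * sp[1])

  overlay <- mask_roi(cs$target_outline$mask | cs$boundary_outline$mask,
                      "overlays")
  prep <- function(i) {
    f <- seq$frames[[i]]
    if (cfg$inpaint_overlays) f <- inpaint_overlay(f, overlay)
    cls <- lapply(cfg$crossline$axes, function(ax)
      detect_crosslines(f, ax, k = cfg$crossline$k,
                        window = cfg$crossline$window))
    list(frame = f, crosslines = cls)
  }
  stage <- function(i, what, expr) {
    tryCatch(expr, error = function(e)
      stop("frame ", i, " [", what, "]: ", conditionMessage(e), call. = FALSE))
  }

  ref <- stage(1, "preprocess", prep(1))
  n <- length(seq)
  out <- data.frame(frame = seq_len(n), time_s = seq$timestamps,
                    dx_mm = 0, dy_mm = 0, theta_deg = 0, score = 1,
                    boundary_warning = FALSE)
  for (i in 2:n) {
    mv <- stage(i, "preprocess", prep(i))
    # reference-frame artifacts leave the ROI; moving-frame artifacts are
    # excluded pairwise inside the similarity, wherever a candidate
    # transform would sample them
    roi <- stage(i, "roi", build_registration_roi(
      filled, ref$crosslines, sp, cfg$skull_band))
    r <- stage(i, "register", register_frame(ref$frame, mv$frame, roi,
                                             center_mm, cfg$search,
                                             moving_crosslines = mv$crosslines))
    out$dx_mm[i] <- r$transform$dx_mm
    out$dy_mm[i] <- r$transform$dy_mm
    out$theta_deg[i] <- r$transform$theta_deg
    out$score[i] <- r$score
    out$boundary_warning[i] <- r$boundary_warning
  }
  class(out) <- c("motion_trace", "data.frame")
  attr(out, "plane_label") <- seq$plane_label
  attr(out, "center_mm") <- center_mm
  attr(out, "contours") <- cs
  out
}

#' Combine three orthogonal-plane traces into a 6-DOF trace
#'
#' Plane-to-axis mapping: the axial trace supplies (lateral, AP, yaw); the
#' sagittal trace supplies (AP, SI, pitch); the coronal trace supplies
#' (lateral, SI, roll). Each translation is therefore seen by two planes;
#' `mode = "mean"` reconciles the redundancy by arithmetic mean,
#' `mode = "both"` additionally keeps the per-plane readouts as
#' `<dof>_<plane>` columns.
#'
#' @param axial,sagittal,coronal `motion_trace` data frames of equal length
#'   (time-aligned).
#' @param mode `"mean"` or `"both"`.
#' @return A `sixdof_trace` data frame: `frame`, `time_s`, `lat_mm`,
#'   `ap_mm`, `si_mm`, `roll_deg`, `pitch_deg`, `yaw_deg`, `score`;
#'   attribute `provenance` records which plane supplied each DOF.
#' @export
planes_to_6dof <- function(axial, sagittal, coronal,
                           mode = c("mean", "both")) {
  mode <- match.arg(mode)
  n <- nrow(axial)
  if (nrow(sagittal) != n || nrow(coronal) != n)
    stop("planes_to_6dof: traces differ in length")
  out <- data.frame(
    frame = axial$frame, time_s = axial$time_s,
    lat_mm = (axial$dx_mm + coronal$dx_mm) / 2,
    ap_mm = (axial$dy_mm + sagittal$dx_mm) / 2,
    si_mm = (sagittal$dy_mm + coronal$dy_mm) / 2,
    roll_deg = coronal$theta_deg,
    pitch_deg = sagittal$theta_deg,
    yaw_deg = axial$theta_deg,
    score = (axial$score + sagittal$score + coronal$score) / 3)
  if (mode == "both") {
    out$lat_mm_axial <- axial$dx_mm
    out$lat_mm_coronal <- coronal$dx_mm
    out$ap_mm_axial <- axial$dy_mm
    out$ap_mm_sagittal <- sagittal$dx_mm
    out$si_mm_sagittal <- sagittal$dy_mm
    out$si_mm_coronal <- coronal$dy_mm
  }
  class(out) <- c("sixdof_trace", "data.frame")
  attr(out, "provenance") <- c(
    lat = "axial+coronal", ap = "axial+sagittal", si = "sagittal+coronal",
    roll = "coronal", pitch = "sagittal", yaw = "axial")
  attr(out, "reconcile") <- mode
  out
}

#' Per-segment maximum-excursion summary
#'
#' For each labeled time window, reports the maximum absolute excursion from
#' baseline (the first frame) per degree of freedom — the shape of a
#' maximum-voluntary-motion table: rotations (roll, pitch, yaw; degrees)
#' then translations (lat, AP/PA, SI; mm).
#'
#' @param trace a `sixdof_trace`.
#' @param segments data frame with `label`, `start_s`, `end_s` (window
#'   `[start_s, end_s]`).
#' @return Data frame: one row per segment, columns `label`, `roll_deg`,
#'   `pitch_deg`, `yaw_deg`, `lat_mm`, `ap_mm`, `si_mm`.
#' @export
summarize_motion <- function(trace, segments) {
  stopifnot(inherits(trace, "sixdof_trace"),
            all(c("label", "start_s", "end_s") %in% names(segments)))
  dofs <- c("roll_deg", "pitch_deg", "yaw_deg", "lat_mm", "ap_mm", "si_mm")
  base <- as.numeric(trace[1, dofs])
  rows <- lapply(seq_len(nrow(segments)), function(s) {
    inwin <- trace$time_s >= segments$start_s[s] &
      trace$time_s <= segments$end_s[s]
    if (!any(inwin))
      stop("summarize_motion: segment '", segments$label[s], "' is empty")
    vapply(seq_along(dofs), function(j)
      max(abs(trace[inwin, dofs[j]] - base[j])), numeric(1))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- dofs
  cbind(label = segments$label, out)
}
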