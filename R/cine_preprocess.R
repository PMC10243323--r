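# Stages (1)-(6) of the planar-cine motion pipeline: crop the system border,
# detect and fill the target contour on the reference frame, inpaint burned-in
# overlays, detect crossline artifacts from interleaved orthogonal-plane
# acquisition, and assemble the skull-band registration ROI. Morphology and
# labeling are delegated to EBImage.

disc_brush <- function(radius_px) {
  r <- max(1L, as.integer(round(radius_px)))
  EBImage::makeBrush(2L * r + 1L, "disc")
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx)  # (row, col)
}

#' Crop the system-added boundary from a cine sequence
#'
#' Delivery consoles export cine frames with a constant-intensity border
#' around the image. `margin = "auto"` detects the border width per side as
#' the run of constant lines equal to the corner intensity of the first
#' frame; an integer (or length-4 integer `c(top, bottom, left, right)`)
#' crops fixed widths.
#'
#' @param seq a [cine_sequence].
#' @param margin `"auto"`, a single integer, or `c(top, bottom, left,
#'   right)` in pixels.
#' @return A [cine_sequence] with all frames cropped identically (spacing
#'   unchanged). Ground-truth attributes are preserved.
#' @export
crop_system_boundary <- function(seq, margin = "auto") {
  stopifnot(inherits(seq, "cine_sequence"))
  px1 <- seq$frames[[1]]$pixels
  d <- dim(px1)
  if (identical(margin, "auto")) {
    m <- detect_constant_border(px1)
  } else {
    margin <- as.integer(margin)
    m <- if (length(margin) == 1) rep(margin, 4) else margin
    if (length(m) != 4 || any(m < 0))
      stop("crop_system_boundary: margin must be >= 0")
  }
  rows <- (1 + m[1]):(d[1] - m[2])
  cols <- (1 + m[3]):(d[2] - m[4])
  if (length(rows) < 1 || length(cols) < 1 || m[1] + m[2] >= d[1] ||
      m[3] + m[4] >= d[2])
    stop("crop_system_boundary: crop window empty or exceeds the frame")
  frames <- lapply(seq$frames, function(f)
    planar_image(f$pixels[rows, cols, drop = FALSE], f$spacing_mm,
                 f$plane_label))
  out <- cine_sequence(frames, seq$frame_rate_fps, seq$timestamps)
  for (a in c("ground_truth", "masks", "crossline_truth"))
    attr(out, a) <- attr(seq, a)
  attr(out, "crop_margin_px") <- m
  out
}

detect_constant_border <- function(px) {
  v <- px[1, 1]
  d <- dim(px)
  run <- function(lines_are_const) {
    r <- 0
    for (i in seq_along(lines_are_const)) {
      if (!lines_are_const[i]) break
      r <- i
    }
    r
  }
  rc <- apply(px, 1, function(x) all(x == v))
  cc <- apply(px, 2, function(x) all(x == v))
  m <- c(run(rc), run(rev(rc)), run(cc), run(rev(cc)))
  # a border must be present on all four sides; otherwise crop nothing
  if (any(m == 0) || any(m >= d / 2)) return(rep(0L, 4))
  as.integer(m)
}

#' Detect target and gating-boundary contours on the reference frame
#'
#' Thresholds the frame (Otsu, within an optional search box), keeps the
#' selected connected component, and returns its 1-px outline (the tracking
#' contour), the filled target, and the gating boundary: the target expanded
#' by `gating_margin_mm` (default 3 mm).
#'
#' @param first_frame a [planar_image].
#' @param config list: `search_box` (`list(rows =, cols =)` index ranges or
#'   `NULL` for the whole frame), `select` (`"largest"` or `"brightest"`
#'   component), `min_area_px`, `gating_margin_mm`, `threshold` (override
#'   the Otsu level on the 0--1 rescaled intensities).
#' @return A `contour_set`: [mask_roi] fields `target_outline`,
#'   `boundary_outline`, `target_filled`, `boundary_filled`;
#'   `rotation_center_px` (row, col) and `rotation_center_mm` (x, y).
#' @export
detect_contours <- function(first_frame, config = list()) {
  stopifnot(inherits(first_frame, "planar_image"))
  cfg <- modifyList(list(search_box = NULL, select = "largest",
                         min_area_px = 25, gating_margin_mm = 3,
                         threshold = NULL), config)
  px <- first_frame$pixels
  rng <- range(px)
  if (diff(rng) <= 0) stop("detect_contours: frame has no intensity contrast")
  sc <- (px - rng[1]) / diff(rng)
  box <- cfg$search_box
  sub <- if (is.null(box)) sc else sc[box$rows, box$cols, drop = FALSE]
  th <- if (is.null(cfg$threshold)) EBImage::otsu(sub, range = c(0, 1))
        else cfg$threshold
  bw <- matrix(FALSE, nrow(sc), ncol(sc))
  if (is.null(box)) bw <- sc > th else bw[box$rows, box$cols] <- sub > th
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  ncomp <- max(lab)
  if (ncomp < 1) stop("detect_contours: no component above threshold")
  areas <- tabulate(lab[lab > 0], nbins = ncomp)
  pick <- if (ncomp == 1) 1L else if (cfg$select == "largest") {
    which.max(areas)
  } else {
    means <- vapply(seq_len(ncomp), function(i) mean(px[lab == i]), numeric(1))
    which.max(means)
  }
  if (areas[pick] < cfg$min_area_px)
    stop("detect_contours: no component above threshold of sufficient area")
  comp <- lab == pick
  filled <- EBImage::imageData(EBImage::fillHull(comp)) > 0
  outline <- filled & !(EBImage::imageData(EBImage::erode(filled,
                                                          disc_brush(1))) > 0)
  margin_px <- cfg$gating_margin_mm / mean(first_frame$spacing_mm)
  bfilled <- EBImage::imageData(EBImage::dilate(filled,
                                                disc_brush(margin_px))) > 0
  boutline <- bfilled & !(EBImage::imageData(EBImage::erode(bfilled,
                                                            disc_brush(1))) > 0)
  ctr <- mask_centroid(filled)
  structure(list(
    target_outline = mask_roi(outline, "target outline"),
    boundary_outline = mask_roi(boutline, "gating boundary outline"),
    target_filled = mask_roi(filled, "target"),
    boundary_filled = mask_roi(bfilled, "gating boundary"),
    rotation_center_px = ctr,
    rotation_center_mm = c((ctr[2] - 1) * first_frame$spacing_mm[2],
                           (ctr[1] - 1) * first_frame$spacing_mm[1])),
    class = "contour_set")
}

#' Fill a closed contour (dilate, fill, erode)
#'
#' Closes gaps up to the dilation radius, fills the interior, and erodes
#' back with the same structuring element. A mask that is already filled is
#' returned unchanged (holes filled). An outline that remains open after
#' dilation raises an error.
#'
#' @param outline a [mask_roi] holding the (possibly gappy) closed curve.
#' @param dilate_radius_px radius of the closing element, pixels.
#' @return List: `filled` ([mask_roi]) and `rotation_center` (row, col)
#'   centroid of the filled mask.
#' @export
fill_contour <- function(outline, dilate_radius_px = 2) {
  check_roi(outline)
  m <- outline$mask
  interior <- EBImage::imageData(EBImage::erode(m, disc_brush(2))) > 0
  if (any(interior)) {
    filled <- EBImage::imageData(EBImage::fillHull(m)) > 0
  } else {
    br <- disc_brush(dilate_radius_px)
    dil <- EBImage::imageData(EBImage::dilate(m, br)) > 0
    fl <- EBImage::imageData(EBImage::fillHull(dil)) > 0
    filled <- EBImage::imageData(EBImage::erode(fl, br)) > 0
    if (sum(filled) <= 2 * sum(m))
      stop("fill_contour: contour is open and cannot be closed by dilation")
  }
  list(filled = mask_roi(filled, "target"),
       rotation_center = mask_centroid(filled))
}

#' Inpaint overlay pixels by iterative neighbor averaging
#'
#' Replaces the pixels under a burned-in graphics overlay with the average
#' of their already-known 8-neighbors, sweeping inward until every overlay
#' pixel is filled. Non-overlay pixels are untouched.
#'
#' @param frame a [planar_image].
#' @param overlay a [mask_roi] of overlay pixels (may be empty).
#' @return A [planar_image].
#' @export
inpaint_overlay <- function(frame, overlay) {
  stopifnot(inherits(frame, "planar_image"))
  check_roi(overlay, frame, require_nonempty = FALSE)
  unknown <- overlay$mask
  if (!any(unknown)) return(frame)
  if (all(unknown)) stop("inpaint_overlay: overlay covers the whole frame")
  px <- frame$pixels
  d <- dim(px)
  known <- !unknown
  vals <- px
  vals[unknown] <- 0
  for (it in seq_len(sum(d))) {
    if (!any(unknown)) break
    ks <- nb8_sum(vals * known)
    kc <- nb8_sum(known * 1)
    fillable <- unknown & kc > 0
    if (!any(fillable)) break
    vals[fillable] <- ks[fillable] / kc[fillable]
    known <- known | fillable
    unknown <- unknown & !fillable
  }
  planar_image(vals, frame$spacing_mm, frame$plane_label)
}

# sum over the 8-neighborhood via shifted copies (zero padding)
nb8_sum <- function(m) {
  d <- dim(m)
  p <- matrix(0, d[1] + 2, d[2] + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1)] <- m
  out <- matrix(0, d[1], d[2])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + p[(2 + dr):(d[1] + 1 + dr), (2 + dc):(d[2] + 1 + dc)]
  }
  out
}

#' Detect crossline artifacts
#'
#' Interleaved orthogonal-plane cine acquisition leaves full bright/dark
#' lines in a frame. Each line's orthogonal-direction intensity sum is
#' compared with the median of its neighboring lines (a window excluding the
#' line itself); a line is flagged when it deviates by more than `k` robust
#' SDs (MAD-based) *and* is a single-line spike: the local maximum of the
#' absolute second difference of the line sums, itself above `k` robust SDs.
#' The spike condition separates one-line artifacts from anatomy, whose
#' line-sum structure is several lines wide.
#'
#' @param frame a [planar_image] with at least 5 lines along `axis`.
#' @param axis `"row"` or `"col"`: the direction the flagged lines run.
#' @param k robust z-score threshold (default 5).
#' @param window half-width of the neighbor window (default 5 lines each
#'   side).
#' @return A `crossline_artifact`: list with `axis`, `indices` (possibly
#'   empty), `strengths` (robust z of each flagged line).
#' @export
detect_crosslines <- function(frame, axis = c("row", "col"), k = 5,
                              window = 5) {
  stopifnot(inherits(frame, "planar_image"))
  axis <- match.arg(axis)
  s <- if (axis == "row") rowSums(frame$pixels) else colSums(frame$pixels)
  n <- length(s)
  if (n < 5) stop("detect_crosslines: need at least 5 lines")
  gmad <- mad(diff(s)) / sqrt(2)  # global noise scale of line sums
  eps <- 1e-9 * (abs(median(s)) + 1)
  z <- vapply(seq_len(n), function(i) {
    nb <- s[setdiff(max(1, i - window):min(n, i + window), i)]
    med <- median(nb)
    scale <- max(mad(nb, center = med), 0.5 * gmad, eps)
    (s[i] - med) / scale
  }, numeric(1))
  # single-line spike test on the second difference of the line sums
  sp <- c(s[1], s, s[n])
  d <- s - (sp[1:n] + sp[3:(n + 2)]) / 2
  zd <- abs(d) / max(mad(d), eps)
  dpad <- c(0, abs(d), 0)
  is_peak <- abs(d) >= pmax(dpad[1:n], dpad[3:(n + 2)])
  idx <- which(abs(z) > k & zd > k & is_peak)
  structure(list(axis = axis, indices = idx, strengths = z[idx]),
            class = "crossline_artifact")
}

#' Build the skull-band registration ROI
#'
#' The registration ROI is an annulus around the target boundary — the
#' filled target dilated by `outer_mm` minus the target eroded by
#' `inner_mm` — which covers the skull ring, minus any detected crossline
#' rows/columns.
#'
#' @param filled [mask_roi] of the filled target.
#' @param crosslines a `crossline_artifact`, a list of them, or `NULL`.
#' @param spacing_mm pixel spacing (row, col) in mm.
#' @param skull_band `c(outer_mm, inner_mm)` dilation/erosion widths.
#' @return A [mask_roi]; error if the result is empty.
#' @export
build_registration_roi <- function(filled, crosslines = NULL,
                                   spacing_mm = c(1.3, 1.3),
                                   skull_band = c(outer_mm = 2,
                                                  inner_mm = 9)) {
  check_roi(filled)
  sp <- mean(spacing_mm)
  dil <- EBImage::imageData(EBImage::dilate(filled$mask,
                                            disc_brush(skull_band[[1]] / sp))) > 0
  ero <- EBImage::imageData(EBImage::erode(filled$mask,
                                           disc_brush(skull_band[[2]] / sp))) > 0
  band <- dil & !ero
  if (!is.null(crosslines)) {
    if (inherits(crosslines, "crossline_artifact"))
      crosslines <- list(crosslines)
    for (cl in crosslines) {
      if (length(cl$indices) == 0) next
      if (cl$axis == "row") band[cl$indices, ] <- FALSE
      else band[, cl$indices] <- FALSE
    }
  }
  if (!any(band))
    stop("build_registration_roi: ROI is empty after crossline exclusion")
  mask_roi(band, "skull band")
}

#' Gating decision for the current target position
#'
#' The beam stays on while the fraction of target pixels outside the gating
#' boundary does not exceed `limit` (default 0: the target must be fully
#' inside the boundary).
#'
#' @param target_now [mask_roi] of the target at the current frame.
#' @param boundary [mask_roi] of the (filled) gating boundary.
#' @param limit tolerated excursion fraction.
#' @return List: `beam_on` (logical), `excursion_fraction`.
#' @export
gate_check <- function(target_now, boundary, limit = 0) {
  check_roi(target_now)
  check_roi(boundary, require_nonempty = FALSE)
  if (!identical(dim(target_now$mask), dim(boundary$mask)))
    stop("gate_check: masks are not congruent")
  frac <- sum(target_now$mask & !boundary$mask) / sum(target_now$mask)
  list(beam_on = frac <= limit, excursion_fraction = frac)
}
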