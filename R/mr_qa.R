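# MR image-quality metrics: ROI statistics, SNR with the Rayleigh-background
# 0.66 correction, percent uniformity / percent integral uniformity (PIU),
# percent-signal ghosting, low-contrast object detectability, and geometric
# accuracy by full-width-at-half-maximum edge finding.

#' Sample statistics over a region of interest
#'
#' @param image a [planar_image] or [volume_image].
#' @param roi a non-empty [mask_roi] congruent with `image`.
#' @return An `roi_stats` list: `mean`, `sd` (n-1 denominator), `max`,
#'   `min`, `count`, `roi_area_cm2` (2D only).
#' @export
roi_stats <- function(image, roi) {
  vals <- if (inherits(image, "planar_image")) {
    check_roi(roi, image)
    image$pixels[roi$mask]
  } else if (inherits(image, "volume_image")) {
    check_roi(roi, image)
    image$voxels[roi$mask]
  } else stop("roi_stats: image must be planar_image or volume_image")
  area <- if (inherits(image, "planar_image"))
    sum(roi$mask) * prod(image$spacing_mm) / 100 else NA_real_
  structure(list(mean = mean(vals), sd = if (length(vals) >= 2) sd(vals) else 0,
                 max = max(vals), min = min(vals), count = length(vals),
                 roi_area_cm2 = area),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> mean %.4g, sd %.4g, range [%.4g, %.4g], n = %d\n",
              x$mean, x$sd, x$min, x$max, x$count))
  invisible(x)
}

#' Signal-to-noise ratio
#'
#' `SNR = signal mean x 0.66 / noise SD`. The 0.66 factor corrects the
#' underestimate of the underlying Gaussian channel noise when the noise SD
#' is measured in a background (air) ROI of a magnitude image, where the
#' noise is Rayleigh distributed.
#'
#' @param signal [roi_stats] of the signal ROI.
#' @param noise [roi_stats] of the noise ROI (sd > 0).
#' @return SNR (scalar).
#' @export
snr <- function(signal, noise) {
  stopifnot(inherits(signal, "roi_stats"), inherits(noise, "roi_stats"))
  if (!(noise$sd > 0)) stop("snr: noise SD must be positive")
  signal$mean * 0.66 / noise$sd
}

#' Percent uniformity
#'
#' `U% = 100 x (1 - (max - min) / (max + min))` over the ROI intensity
#' extremes.
#'
#' @param roi [roi_stats] of the uniformity ROI (`max + min > 0`).
#' @return U% in `[0, 100]`.
#' @export
percent_uniformity <- function(roi) {
  stopifnot(inherits(roi, "roi_stats"))
  if (!(roi$max + roi$min > 0))
    stop("percent_uniformity: max + min must be positive")
  100 * (1 - (roi$max - roi$min) / (roi$max + roi$min))
}

#' Percent integral uniformity (ACR)
#'
#' Same functional form as [percent_uniformity()], applied to the mean
#' intensities of the ACR low- and high-signal 1 cm^2 ROIs on slice 7.
#'
#' @param low_mean,high_mean low/high ROI means, `high_mean >= low_mean > 0`.
#' @param digits decimals for report parity (default 1; `NA` = unrounded).
#' @return PIU in percent.
#' @export
piu <- function(low_mean, high_mean, digits = 1) {
  if (!(low_mean > 0)) stop("piu: low_mean must be positive")
  if (low_mean > high_mean) stop("piu: low_mean exceeds high_mean")
  v <- 100 * (1 - (high_mean - low_mean) / (high_mean + low_mean))
  if (is.na(digits)) v else round(v, digits)
}

#' Percent-signal ghosting ratio (ACR)
#'
#' `|((top + bottom) - (left + right)) / (2 x large ROI mean)|` from the
#' four edge ROI means and the large in-phantom ROI mean on slice 7.
#'
#' @param top,bottom,left,right edge ROI means.
#' @param large_roi_mean large ROI mean (> 0).
#' @param digits decimals for report parity (default 3; `NA` = unrounded).
#' @return Ghosting ratio (unitless).
#' @export
ghosting_ratio <- function(top, bottom, left, right, large_roi_mean,
                           digits = 3) {
  if (!(large_roi_mean > 0))
    stop("ghosting_ratio: large ROI mean must be positive")
  v <- abs(((top + bottom) - (left + right)) / (2 * large_roi_mean))
  if (is.na(digits)) v else round(v, digits)
}

#' Automated low-contrast object detectability count for one slice
#'
#' A spoke counts when all three of its circles are discernible. The human
#' judgment is surrogated by a contrast-to-noise rule: circle mean minus
#' local background mean >= `k` x background SD, with the local background
#' taken from an annulus around each circle.
#'
#' @param slice_image a [planar_image].
#' @param template data frame with `spoke`, `circle`, `row`, `col`,
#'   `radius_px` (as returned by [make_low_contrast_slice()]).
#' @param k detection threshold in background SDs (default 3).
#' @return Integer count of detectable spokes, 0--10.
#' @export
low_contrast_count <- function(slice_image, template, k = 3) {
  stopifnot(inherits(slice_image, "planar_image"))
  need <- c("spoke", "circle", "row", "col", "radius_px")
  if (!all(need %in% names(template)))
    stop("low_contrast_count: template must have columns ",
         paste(need, collapse = ", "))
  if (!setequal(unique(template$spoke), 1:10) ||
      any(table(template$spoke) != 3))
    stop("low_contrast_count: template must define 10 spokes of 3 circles")
  px <- slice_image$pixels
  d <- dim(px)
  rr <- row(px); cc <- col(px)
  detectable <- vapply(seq_len(nrow(template)), function(i) {
    r0 <- template$row[i]; c0 <- template$col[i]; rad <- template$radius_px[i]
    if (r0 < 1 || c0 < 1 || r0 > d[1] || c0 > d[2])
      stop("low_contrast_count: template circle outside the slice")
    dist2 <- (rr - r0)^2 + (cc - c0)^2
    inside <- dist2 <= (0.8 * rad)^2
    annulus <- dist2 > (rad + 2)^2 & dist2 <= (rad + 6)^2
    bg <- px[annulus]
    (mean(px[inside]) - mean(bg)) >= k * max(sd(bg), 1e-12)
  }, logical(1))
  ok <- tapply(detectable, template$spoke, all)
  as.integer(sum(ok))
}

#' Full low-contrast object detectability score
#'
#' Sum of the per-slice spoke counts for ACR slices 8--11.
#'
#' @param per_slice_counts four integers in 0--10.
#' @return Integer cumulative score.
#' @export
full_lcod_score <- function(per_slice_counts) {
  if (length(per_slice_counts) != 4)
    stop("full_lcod_score: need 4 per-slice counts (slices 8-11)")
  if (any(per_slice_counts < 0 | per_slice_counts > 10) ||
      any(per_slice_counts != round(per_slice_counts)))
    stop("full_lcod_score: counts must be integers in 0..10")
  as.integer(sum(per_slice_counts))
}

#' Geometric accuracy: phantom lengths by half-maximum edge finding
#'
#' Measures the full-width-at-half-maximum distance between opposing phantom
#' edges along image rows/columns through the phantom centroid, with
#' sub-pixel linear interpolation of the half-maximum crossings.
#'
#' @param image a [planar_image], or a [volume_image] with `axes` from
#'   `"x"`, `"y"`, `"z"` (profiles through the volume's center voxel).
#' @param axes for planar images, any of `"row"` (vertical extent) and
#'   `"col"` (horizontal extent); for volumes, `"x"`, `"y"`, `"z"`.
#' @return Named numeric vector of lengths in mm.
#' @export
geometric_lengths <- function(image, axes = c("row", "col")) {
  if (inherits(image, "planar_image")) {
    px <- image$pixels
    if (quantile(px, 0.99) <= quantile(px, 0.01))
      stop("geometric_lengths: edge not found (flat image)")
    thr <- (quantile(px, 0.99) + quantile(px, 0.01)) / 2
    ctr <- mask_centroid(px > thr)
    out <- vapply(axes, function(ax) {
      prof <- profile_through(px, ctr, ax)
      fwhm_length(prof, if (ax == "row") image$spacing_mm[1]
                        else image$spacing_mm[2])
    }, numeric(1))
    return(stats::setNames(out, axes))
  }
  stopifnot(inherits(image, "volume_image"))
  vx <- image$voxels
  d <- dim(vx)
  if (quantile(vx, 0.99) <= quantile(vx, 0.01))
    stop("geometric_lengths: edge not found (flat image)")
  thr <- (quantile(vx, 0.99) + quantile(vx, 0.01)) / 2
  idx <- which(vx > thr, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  out <- vapply(axes, function(ax) {
    prof <- switch(ax,
                   x = vx[, ctr[2], ctr[3]],
                   y = vx[ctr[1], , ctr[3]],
                   z = vx[ctr[1], ctr[2], ],
                   stop("geometric_lengths: volume axes are x, y, z"))
    fwhm_length(prof, image$spacing_mm[match(ax, c("x", "y", "z"))])
  }, numeric(1))
  stats::setNames(out, axes)
}

profile_through <- function(px, ctr_rc, axis) {
  # average 3 adjacent central profiles for noise robustness
  d <- dim(px)
  if (axis == "row") {
    c0 <- round(ctr_rc[2])
    cols <- unique(pmin(pmax(c0 + (-1:1), 1), d[2]))
    rowMeans(px[, cols, drop = FALSE])
  } else if (axis == "col") {
    r0 <- round(ctr_rc[1])
    rows <- unique(pmin(pmax(r0 + (-1:1), 1), d[1]))
    colMeans(px[rows, , drop = FALSE])
  } else stop("geometric_lengths: planar axes are 'row' and 'col'")
}

fwhm_length <- function(prof, spacing) {
  lo <- as.numeric(quantile(prof, 0.02))
  hi <- as.numeric(quantile(prof, 0.98))
  if (hi <= lo) stop("geometric_lengths: edge not found (flat profile)")
  half <- (lo + hi) / 2
  above <- prof >= half
  if (!any(above)) stop("geometric_lengths: edge not found")
  i1 <- which(above)[1]
  i2 <- tail(which(above), 1)
  # sub-pixel linear interpolation at both crossings
  left <- if (i1 == 1) 1 else
    i1 - (prof[i1] - half) / (prof[i1] - prof[i1 - 1])
  right <- if (i2 == length(prof)) i2 else
    i2 + (prof[i2] - half) / (prof[i2] - prof[i2 + 1])
  (right - left) * spacing
}

#' Assemble an ACR-style report
#'
#' Bundles the per-test results in the shape of an ACR summary table row
#' set: per-slice low-contrast counts and their sum, geometric lengths,
#' uniformity low/high/PIU, and ghosting ROI means with the ghosting ratio.
#'
#' @param lcod_counts named or plain vector of 4 counts (slices 8--11).
#' @param lengths_mm named vector of measured lengths.
#' @param uniformity_low,uniformity_high low/high ROI means.
#' @param ghost list or vector with `top`, `bottom`, `left`, `right`,
#'   `large_roi`.
#' @param spatial_resolution_mm human-read resolution-insert value
#'   (reported, not computed).
#' @return An `acr_report` list mirroring the table rows.
#' @export
acr_report <- function(lcod_counts, lengths_mm = NULL, uniformity_low,
                       uniformity_high, ghost, spatial_resolution_mm = NA) {
  g <- as.list(ghost)
  structure(list(
    lcod_slice_counts = as.integer(lcod_counts),
    lcod_full_score = full_lcod_score(lcod_counts),
    geometric_lengths_mm = lengths_mm,
    spatial_resolution_mm = spatial_resolution_mm,
    uniformity_low = uniformity_low,
    uniformity_high = uniformity_high,
    piu_pct = piu(uniformity_low, uniformity_high),
    ghost_rois = g,
    ghosting_ratio = ghosting_ratio(g$top, g$bottom, g$left, g$right,
                                    g$large_roi)),
    class = "acr_report")
}

#' @export
print.acr_report <- function(x, ...) {
  cat("<acr_report>\n")
  cat("  LCOD slices 8-11:", paste(x$lcod_slice_counts, collapse = ", "),
      "| full score:", x$lcod_full_score, "\n")
  if (!is.null(x$geometric_lengths_mm))
    cat("  lengths (mm):",
        paste(sprintf("%s=%.2f", names(x$geometric_lengths_mm),
                      x$geometric_lengths_mm), collapse = ", "), "\n")
  cat(sprintf("  uniformity low/high: %.2f / %.2f -> PIU %.1f%%\n",
              x$uniformity_low, x$uniformity_high, x$piu_pct))
  cat(sprintf("  ghosting ratio: %.3f\n", x$ghosting_ratio))
  invisible(x)
}
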