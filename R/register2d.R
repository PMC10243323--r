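# Step (7) of the cine pipeline: rigid 2D registration of each frame to the
# reference frame by exhaustive coarse-to-fine search over (dx, dy, theta),
# scored by the Pearson correlation between the reference ROI pixels and the
# moving image sampled (bilinear) at the forward-transformed ROI locations.

#' Pearson product-moment similarity
#'
#' @param a,b equal-length numeric vectors (length >= 2), both with nonzero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("pearson_similarity: need equal lengths >= 2")
  if (sd(a) == 0 || sd(b) == 0)
    stop("pearson_similarity: zero variance (untextured ROI)")
  stats::cor(a, b)
}

#' Registration search configuration
#'
#' Three-level coarse-to-fine exhaustive grid search. Level 1 scans the full
#' range at the coarse step; each subsequent level scans +/- the previous
#' step around the incumbent at a step `refine` times finer. The defaults
#' (range 10 mm / 5 deg, coarse step 2.5, refine 5, 3 levels) end at 0.1 mm
#' and 0.1 deg.
#'
#' @param range_mm,range_deg half-width of the level-1 search.
#' @param coarse_step_mm,coarse_step_deg level-1 grid step.
#' @param levels number of levels.
#' @param refine step refinement factor per level.
#' @param max_points maximum ROI sample points (regular stride subsampling
#'   beyond; the skull band typically holds a few thousand pixels).
#' @param smooth_sigma_px Gaussian pre-blur (pixels) applied to both frames
#'   before scoring. A symmetric sub-pixel blur suppresses the rasterization
#'   bias that otherwise skews sub-degree rotation estimates; 0 disables.
#' @return A list of search parameters.
#' @export
search_config <- function(range_mm = 10, range_deg = 5, coarse_step_mm = 2.5,
                          coarse_step_deg = 2.5, levels = 3, refine = 5,
                          max_points = 1500, smooth_sigma_px = 0.8) {
  list(range_mm = range_mm, range_deg = range_deg,
       coarse_step_mm = coarse_step_mm, coarse_step_deg = coarse_step_deg,
       levels = levels, refine = refine, max_points = max_points,
       smooth_sigma_px = smooth_sigma_px)
}

# Batch-score candidate transforms; cand columns dx, dy, theta_deg.
# bad_lines: list(bad_row =, bad_col =) logical vectors flagging moving-frame
# crossline lines whose samples are dropped pairwise.
score_candidates <- function(moving, ref_vals, px, py, cand, center_mm,
                             spacing_mm, min_valid, bad_lines = NULL) {
  cm <- cbind(cand[, 1], cand[, 2], cand[, 3] * pi / 180)
  if (is.null(bad_lines))
    bad_lines <- list(bad_row = logical(0), bad_col = logical(0))
  cpp_score2d(moving$pixels, ref_vals, px, py, cm, center_mm[1],
              center_mm[2], spacing_mm[1], spacing_mm[2], min_valid,
              bad_lines$bad_row, bad_lines$bad_col)
}

# Deterministic argmax with tie-breaking toward the smallest transform:
# lexicographic (|theta|, |dx| + |dy|).
pick_best <- function(cand, scores, tol = 1e-12) {
  s <- ifelse(is.na(scores), -Inf, scores)
  best <- max(s)
  if (!is.finite(best)) stop("register_frame: no valid overlap in the search")
  ties <- which(s >= best - tol)
  if (length(ties) > 1) {
    o <- order(abs(cand[ties, 3]), abs(cand[ties, 1]) + abs(cand[ties, 2]))
    ties <- ties[o]
  }
  ties[1]
}

#' Register a moving frame to the reference frame
#'
#' Finds the in-plane rigid transform (rotation about `center_mm`)
#' maximizing the Pearson similarity between the reference ROI and the
#' moving image sampled at transformed ROI locations. Exhaustive
#' coarse-to-fine search; ties resolved toward the smallest transform.
#'
#' @param ref,moving [planar_image] frames of equal shape and spacing.
#' @param roi [mask_roi] on the reference frame (non-empty).
#' @param center_mm rotation center `(x, y)` in mm; default: ROI centroid.
#' @param search a [search_config()].
#' @param moving_crosslines `NULL`, a `crossline_artifact`, or a list of
#'   them, flagging corrupted lines of the *moving* frame: any sample whose
#'   transformed location falls on a flagged line is excluded from the
#'   similarity, whatever the candidate transform.
#' @return List: `transform` ([rigid2d]), `score`, `boundary_warning`
#'   (`TRUE` when the optimum touched the level-1 search boundary, i.e. the
#'   motion may exceed the search range).
#' @export
register_frame <- function(ref, moving, roi, center_mm = NULL,
                           search = search_config(),
                           moving_crosslines = NULL) {
  stopifnot(inherits(ref, "planar_image"), inherits(moving, "planar_image"))
  check_roi(roi, ref)
  sigma <- if (is.null(search$smooth_sigma_px)) 0 else search$smooth_sigma_px
  # the pre-blur spreads a corrupted line into its neighbors: widen the
  # exclusion by the blur support
  bad_lines <- crossline_bad_lines(moving_crosslines, dim(moving$pixels),
                                   pad = ceiling(2 * sigma))
  if (!is.null(search$smooth_sigma_px) && search$smooth_sigma_px > 0) {
    ref$pixels <- EBImage::imageData(
      EBImage::gblur(ref$pixels, search$smooth_sigma_px))
    moving$pixels <- EBImage::imageData(
      EBImage::gblur(moving$pixels, search$smooth_sigma_px))
  }
  idx <- which(roi$mask, arr.ind = TRUE)
  if (!is.null(search$max_points) && nrow(idx) > search$max_points)
    idx <- idx[seq(1, nrow(idx),
                   by = ceiling(nrow(idx) / search$max_points)), ,
               drop = FALSE]
  sp <- ref$spacing_mm
  px <- (idx[, 2] - 1) * sp[2]
  py <- (idx[, 1] - 1) * sp[1]
  ref_vals <- ref$pixels[idx]
  if (sd(ref_vals) == 0) stop("register_frame: untextured ROI")
  if (is.null(center_mm)) center_mm <- c(mean(px), mean(py))
  min_valid <- max(10, floor(0.5 * length(ref_vals)))

  step_mm <- search$coarse_step_mm
  step_deg <- search$coarse_step_deg
  gx <- seq(-search$range_mm, search$range_mm, by = step_mm)
  gt <- seq(-search$range_deg, search$range_deg, by = step_deg)
  cand <- as.matrix(expand.grid(dx = gx, dy = gx, th = gt))
  sc <- score_candidates(moving, ref_vals, px, py, cand, center_mm, sp,
                         min_valid, bad_lines)
  b <- pick_best(cand, sc)
  best <- cand[b, ]
  warn <- any(abs(best[1:2]) >= search$range_mm - 1e-9) ||
    abs(best[3]) >= search$range_deg - 1e-9
  for (lev in seq_len(search$levels - 1)) {
    off_mm <- seq(-step_mm, step_mm, by = step_mm / search$refine)
    off_deg <- seq(-step_deg, step_deg, by = step_deg / search$refine)
    cand <- as.matrix(expand.grid(dx = best[1] + off_mm,
                                  dy = best[2] + off_mm,
                                  th = best[3] + off_deg))
    sc <- score_candidates(moving, ref_vals, px, py, cand, center_mm, sp,
                           min_valid, bad_lines)
    b <- pick_best(cand, sc)
    best <- cand[b, ]
    step_mm <- step_mm / search$refine
    step_deg <- step_deg / search$refine
  }
  list(transform = rigid2d(best[[1]], best[[2]], best[[3]],
                           center_mm = center_mm),
       score = sc[b], boundary_warning = warn)
}

# logical per-row/per-col flags (0-based C++ indexing) for moving-frame
# crossline lines; `pad` widens each flagged line on both sides
crossline_bad_lines <- function(crosslines, dims, pad = 0) {
  if (is.null(crosslines)) return(NULL)
  if (inherits(crosslines, "crossline_artifact")) crosslines <- list(crosslines)
  bad_row <- logical(dims[1])
  bad_col <- logical(dims[2])
  hit <- FALSE
  for (cl in crosslines) {
    if (length(cl$indices) == 0) next
    hit <- TRUE
    idx <- unique(pmin(pmax(rep(cl$indices, each = 2 * pad + 1) +
                              (-pad):pad, 1),
                       if (cl$axis == "row") dims[1] else dims[2]))
    if (cl$axis == "row") bad_row[idx] <- TRUE
    else bad_col[idx] <- TRUE
  }
  if (!hit) return(NULL)
  list(bad_row = bad_row, bad_col = bad_col)
}
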