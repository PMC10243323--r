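# 6-DOF rigid registration of repeat-setup volumes by histogram-based mutual
# information over an ROI (the paper's workflow aligns repeat scans on the
# lateral ventricles), and the pooled inter-fraction variability summary.

#' 3D registration configuration
#'
#' @param bins joint-histogram bins per axis.
#' @param max_points maximum ROI sample points (regular subsampling beyond).
#' @param range_mm,range_deg search bounds per DOF.
#' @param steps_mm,steps_deg coordinate-descent step schedule (coarse to
#'   fine); the final steps set the resolution (defaults end at 0.1 mm /
#'   0.1 deg).
#' @param max_sweeps maximum descent sweeps per step level.
#' @return List of parameters.
#' @export
#' @param presmooth per-level number of 3x3x3 box-blur passes applied to
#'   both volumes before sampling (recycled across levels; three passes
#'   approximate a Gaussian of ~1 voxel SD). Smoothing suppresses the
#'   grid-aligned local MI extrema that interpolated noise produces; the
#'   fine levels use less of it so weakly determined rotations keep their
#'   high-frequency information.
register3d_config <- function(bins = 32, max_points = 30000, range_mm = 15,
                              range_deg = 8,
                              steps_mm = c(3, 1, 0.3, 0.1, 0.05),
                              steps_deg = c(3, 1, 0.3, 0.1, 0.05),
                              max_sweeps = 8,
                              presmooth = c(3, 3, 1, 1, 0)) {
  list(bins = bins, max_points = max_points, range_mm = range_mm,
       range_deg = range_deg, steps_mm = steps_mm, steps_deg = steps_deg,
       max_sweeps = max_sweeps, presmooth = presmooth)
}

# separable 3x3x3 box blur with edge replication
smooth3_box <- function(a, passes) {
  d <- dim(a)
  shift <- function(a, ax, k) {
    i <- pmin(pmax(seq_len(d[ax]) + k, 1), d[ax])
    switch(ax, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  for (p in seq_len(passes))
    for (ax in 1:3)
      a <- (shift(a, ax, -1) + a + shift(a, ax, 1)) / 3
  a
}

#' Rigid 6-DOF registration by mutual information
#'
#' Maximizes the mutual information between the fixed image's ROI samples
#' and the moving volume sampled (trilinear) at forward-transformed ROI
#' locations. The translation is initialized from the foreground
#' center-of-mass offset; the six parameters are then refined by
#' coordinate descent over a coarse-to-fine step schedule. MI is invariant
#' to monotone intensity rescaling of either volume.
#'
#' @param fixed,moving [volume_image] objects on the same grid geometry.
#' @param roi [mask_roi] on `fixed` (e.g. a ventricle surround); `NULL`
#'   uses the foreground bounding box.
#' @param config a [register3d_config()].
#' @param fixed_id,moving_id identifiers for the report.
#' @return A `setup_match`: `transform` ([rigid3d] mapping fixed anatomy
#'   onto the moving scan), `score` (MI), `boundary_warning`,
#'   `roi_label`, `fixed_id`, `moving_id`.
#' @export
rigid_register_3d <- function(fixed, moving, roi = NULL,
                              config = register3d_config(),
                              fixed_id = "fixed", moving_id = "moving") {
  stopifnot(inherits(fixed, "volume_image"), inherits(moving, "volume_image"))
  d <- dim(fixed$voxels)
  sp <- fixed$spacing_mm
  nlev <- max(length(config$steps_mm), length(config$steps_deg))
  lev_smooth <- rep_len(config$presmooth, nlev)
  smoothed <- new.env(parent = emptyenv())
  volumes_at <- function(passes) {
    key <- as.character(passes)
    if (is.null(smoothed[[key]]))
      smoothed[[key]] <- list(
        f = if (passes > 0) smooth3_box(fixed$voxels, passes)
            else fixed$voxels,
        m = if (passes > 0) smooth3_box(moving$voxels, passes)
            else moving$voxels)
    smoothed[[key]]
  }
  v1 <- volumes_at(lev_smooth[1])
  if (is.null(roi)) {
    thr <- (max(v1$f) + min(v1$f)) / 2
    roi <- mask_roi(v1$f > thr, "foreground")
  }
  check_roi(roi, fixed)
  idx <- which(roi$mask)
  if (length(idx) > config$max_points) {
    stride <- ceiling(length(idx) / config$max_points)
    idx <- idx[seq(1, length(idx), by = stride)]
  }
  ai <- arrayInd(idx, d)
  pts <- cbind((ai[, 1] - 1) * sp[1], (ai[, 2] - 1) * sp[2],
               (ai[, 3] - 1) * sp[3])
  # with few samples, shrink the histogram so joint cells stay populated;
  # small-sample MI otherwise rewards misalignments that spread the joint
  bins <- min(config$bins, max(8L, floor(sqrt(length(idx) / 8))))
  center <- (d - 1) / 2 * sp
  min_valid <- max(100, floor(0.3 * length(idx)))

  vols <- NULL
  fbin <- NULL
  mrng <- NULL
  set_level <- function(passes) {
    vols <<- volumes_at(passes)
    fvals <- vols$f[idx]
    frng <- range(fvals)
    if (diff(frng) <= 0) stop("rigid_register_3d: flat fixed ROI")
    fbin <<- pmin(as.integer((fvals - frng[1]) / diff(frng) * bins),
                  bins - 1L)
    mrng <<- range(vols$m)
  }
  mi_of <- function(cand) {
    cpp_mi3d(fbin, pts, vols$m, as.integer(d), moving$spacing_mm,
             cbind(cand[, 1:3, drop = FALSE],
                   cand[, 4:6, drop = FALSE] * pi / 180),
             center, bins, mrng[1], mrng[2], min_valid)
  }
  set_level(lev_smooth[1])

  # center-of-mass initialization of the translation
  com <- function(v, s) {
    thr <- (max(v) + min(v)) / 2
    aw <- arrayInd(which(v > thr), d)
    colMeans(aw - 1) * s
  }
  cur <- c(com(vols$m, moving$spacing_mm) - com(vols$f, sp), 0, 0, 0)
  cur[1:3] <- pmax(pmin(cur[1:3], config$range_mm), -config$range_mm)
  cur_mi <- mi_of(matrix(cur, 1))

  for (lev in seq_len(nlev)) {
    if (lev > 1 && lev_smooth[lev] != lev_smooth[lev - 1]) {
      set_level(lev_smooth[lev])
      cur_mi <- mi_of(matrix(cur, 1))
    }
    st <- c(rep(config$steps_mm[min(lev, length(config$steps_mm))], 3),
            rep(config$steps_deg[min(lev, length(config$steps_deg))], 3))
    for (sweep in seq_len(config$max_sweeps)) {
      improved <- FALSE
      for (dof in 1:6) {
        lim <- if (dof <= 3) config$range_mm else config$range_deg
        offs <- st[dof] * c(-2, -1, 1, 2)
        vals <- cur[dof] + offs
        vals <- vals[abs(vals) <= lim]
        if (!length(vals)) next
        cand <- matrix(rep(cur, each = length(vals)), ncol = 6)
        cand[, dof] <- vals
        scores <- mi_of(cand)
        scores[is.na(scores)] <- -Inf
        j <- which.max(scores)
        if (scores[j] > cur_mi + 1e-9) {
          cur <- cand[j, ]
          cur_mi <- scores[j]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  if (!is.finite(cur_mi) || cur_mi < 0.05)
    stop("rigid_register_3d: flat similarity, registration failure")
  warn <- any(abs(cur[1:3]) >= config$range_mm - 1e-9) ||
    any(abs(cur[4:6]) >= config$range_deg - 1e-9)
  structure(list(
    transform = rigid3d(cur[1], cur[2], cur[3], cur[4], cur[5], cur[6]),
    score = cur_mi, boundary_warning = warn, roi_label = roi$label,
    fixed_id = fixed_id, moving_id = moving_id),
    class = "setup_match")
}

#' @export
print.setup_match <- function(x, ...) {
  cat(sprintf("<setup_match> %s -> %s (ROI '%s'), MI %.3f\n", x$moving_id,
              x$fixed_id, x$roi_label, x$score))
  print(x$transform)
  invisible(x)
}

#' Pairwise inter-fraction setup variability
#'
#' Registers every later scan to every earlier scan (for 3 scans: 2 to 1,
#' 3 to 1, 3 to 2) and summarizes the pooled absolute per-DOF changes.
#'
#' @param volumes ordered list of >= 2 [volume_image] scans.
#' @param roi [mask_roi] on the first scan used for every match.
#' @param config a [register3d_config()].
#' @param ids scan identifiers (default `1..n`).
#' @return List: `matches` (list of `setup_match`), `summary` (see
#'   [variability_summary()]), `failures` (per-pair error messages, if any).
#' @export
pairwise_setup_variability <- function(volumes, roi = NULL,
                                       config = register3d_config(),
                                       ids = NULL) {
  stopifnot(is.list(volumes), length(volumes) >= 2)
  n <- length(volumes)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  matches <- list()
  failures <- character(0)
  for (j in 2:n) for (i in seq_len(j - 1)) {
    m <- tryCatch(
      rigid_register_3d(volumes[[i]], volumes[[j]], roi, config,
                        fixed_id = ids[i], moving_id = ids[j]),
      error = function(e) conditionMessage(e))
    if (inherits(m, "setup_match")) matches[[length(matches) + 1]] <- m
    else failures <- c(failures,
                       sprintf("%s -> %s: %s", ids[j], ids[i], m))
  }
  vals <- do.call(rbind, lapply(matches, function(m)
    as_vector_rigid3d(m$transform)))
  colnames(vals) <- c("lat_mm", "ap_mm", "si_mm", "roll_deg", "pitch_deg",
                      "yaw_deg")
  list(matches = matches, summary = variability_summary(vals),
       failures = failures)
}

#' Variability summary over absolute per-DOF values
#'
#' Average, SD, minimum and maximum of the absolute values pooled across
#' matches (and subjects) — the shape of an inter-fraction setup
#' variability table. All reported quantities are >= 0.
#'
#' @param values matrix/data frame, one row per match, one column per DOF.
#' @return Data frame with rows `average`, `sd`, `min`, `max`.
#' @export
variability_summary <- function(values) {
  values <- abs(as.matrix(values))
  stopifnot(nrow(values) >= 1)
  out <- rbind(average = colMeans(values),
               sd = apply(values, 2, function(x)
                 if (length(x) >= 2) sd(x) else 0),
               min = apply(values, 2, min),
               max = apply(values, 2, max))
  as.data.frame(out)
}
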