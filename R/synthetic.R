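# Synthetic digital phantoms: head cross-sections (bright skull ring, brain,
# dark ventricles) under rigid motion with MR-like noise and crossline
# artifacts, plus uniform and low-contrast QA phantom slices. Every
# generator is deterministic given `seed` and returns the ground truth it
# used, so the tracking and registration modules can be validated without
# clinical data.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# MR magnitude noise: Rician inside anatomy, Rayleigh-like in air background,
# from two additive Gaussian quadrature channels of standard deviation `sd`.
# The Rayleigh background has SD ~ 0.655 sd, which is what the 0.66 factor in
# the SNR formula compensates for.
add_mr_noise <- function(pixels, sd) {
  if (sd <= 0) return(pixels)
  n <- length(pixels)
  sqrt((pixels + rnorm(n, 0, sd))^2 + rnorm(n, 0, sd)^2)
}

#' Head phantom specification
#'
#' Geometry and intensity parameters of the synthetic head cross-section.
#' Defaults emulate an adult head imaged with the brain-coil cine preset:
#' 1.3 mm pixels, an elliptical skull ring (bright) around brain parenchyma
#' (mid grey) containing two dark lateral ventricles.
#'
#' @param n_row,n_col image size in pixels.
#' @param spacing_mm pixel size (isotropic), mm. 1.3 mm is the brain-coil
#'   cine resolution; 3.5 mm emulates the torso-coil cine.
#' @param skull_semiaxes_mm outer skull ellipse semi-axes (lateral, AP/SI).
#' @param skull_thickness_mm skull ring thickness.
#' @param ventricle_semiaxes_mm ventricle ellipse semi-axes.
#' @param ventricle_offset_mm lateral offset of each ventricle from midline.
#' @param intensities named vector: background, brain, skull, ventricle.
#' @param noise_sd Gaussian channel noise SD (see note on Rician model).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_row = 160, n_col = 160, spacing_mm = 1.3,
                         skull_semiaxes_mm = c(65, 80),
                         skull_thickness_mm = 6,
                         ventricle_semiaxes_mm = c(6, 18),
                         ventricle_offset_mm = 13,
                         intensities = c(background = 0, brain = 120,
                                         skull = 200, ventricle = 40),
                         noise_sd = 4) {
  spec <- list(n_row = n_row, n_col = n_col, spacing_mm = spacing_mm,
               skull_semiaxes_mm = skull_semiaxes_mm,
               skull_thickness_mm = skull_thickness_mm,
               ventricle_semiaxes_mm = ventricle_semiaxes_mm,
               ventricle_offset_mm = ventricle_offset_mm,
               intensities = intensities, noise_sd = noise_sd)
  inner <- skull_semiaxes_mm - skull_thickness_mm
  if (any(skull_semiaxes_mm <= 0) || any(inner <= 0))
    stop("phantom_spec: skull geometry must be positive")
  if (any(ventricle_semiaxes_mm <= 0))
    stop("phantom_spec: ventricle geometry must be positive")
  if (ventricle_offset_mm + ventricle_semiaxes_mm[1] >= inner[1] ||
      ventricle_semiaxes_mm[2] >= inner[2])
    stop("phantom_spec: ventricles must nest strictly inside the brain")
  class(spec) <- "phantom_spec"
  spec
}

ellipse_mask <- function(n_row, n_col, spacing, center_mm, semi_mm) {
  x <- (seq_len(n_col) - 1) * spacing
  y <- (seq_len(n_row) - 1) * spacing
  xx <- matrix(x, n_row, n_col, byrow = TRUE)
  yy <- matrix(y, n_row, n_col)
  ((xx - center_mm[1]) / semi_mm[1])^2 + ((yy - center_mm[2]) / semi_mm[2])^2 <= 1
}

#' Generate a synthetic head slice with ground-truth tissue masks
#'
#' @param spec a [phantom_spec].
#' @param plane plane label for the returned image.
#' @param noise_sd override the spec's noise SD (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @return List: `image` ([planar_image]), and [mask_roi] elements `head`
#'   (skull + interior), `skull` (ring only), `brain`, `ventricles`, plus
#'   `center_mm`, the head center in mm.
#' @export
make_head_slice <- function(spec = phantom_spec(), plane = "axial",
                            noise_sd = spec$noise_sd, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  ctr <- c((spec$n_col - 1) / 2, (spec$n_row - 1) / 2) * sp
  outer <- ellipse_mask(spec$n_row, spec$n_col, sp, ctr, spec$skull_semiaxes_mm)
  inner <- ellipse_mask(spec$n_row, spec$n_col, sp, ctr,
                        spec$skull_semiaxes_mm - spec$skull_thickness_mm)
  v1 <- ellipse_mask(spec$n_row, spec$n_col, sp,
                     ctr + c(-spec$ventricle_offset_mm, 0),
                     spec$ventricle_semiaxes_mm)
  v2 <- ellipse_mask(spec$n_row, spec$n_col, sp,
                     ctr + c(spec$ventricle_offset_mm, 0),
                     spec$ventricle_semiaxes_mm)
  vent <- (v1 | v2) & inner
  iv <- spec$intensities
  px <- matrix(iv[["background"]], spec$n_row, spec$n_col)
  px[outer] <- iv[["skull"]]
  px[inner] <- iv[["brain"]]
  px[vent] <- iv[["ventricle"]]
  if (noise_sd > 0) px <- with_seed(seed, add_mr_noise(px, noise_sd))
  list(image = planar_image(px, sp, plane),
       head = mask_roi(outer, "head"),
       skull = mask_roi(outer & !inner, "skull"),
       brain = mask_roi(inner & !vent, "brain"),
       ventricles = mask_roi(vent, "ventricles"),
       center_mm = ctr)
}

#' Motion schedules
#'
#' A motion schedule is a list of per-frame rigid transforms plus a segment
#' label per frame; it is the ground truth stored with every generated cine
#' or volume series.
#'
#' @param transforms list of [rigid2d] or [rigid3d], one per frame.
#' @param labels character segment label per frame (default "all").
#' @return A `motion_schedule` object.
#' @export
motion_schedule <- function(transforms, labels = NULL) {
  stopifnot(is.list(transforms), length(transforms) >= 1)
  if (is.null(labels)) labels <- rep("all", length(transforms))
  if (length(labels) != length(transforms))
    stop("motion_schedule: one label per frame required")
  structure(list(transforms = transforms, labels = as.character(labels)),
            class = "motion_schedule")
}

#' @export
length.motion_schedule <- function(x) length(x$transforms)

#' @rdname motion_schedule
#' @param n_frames number of frames.
#' @export
schedule_static <- function(n_frames) {
  motion_schedule(replicate(n_frames, rigid2d(), simplify = FALSE))
}

#' @rdname motion_schedule
#' @param at frame index at which the step occurs (frames `>= at` moved).
#' @param dx_mm,dy_mm,theta_deg step amplitude.
#' @export
schedule_step <- function(n_frames, at, dx_mm = 0, dy_mm = 0, theta_deg = 0) {
  tfs <- lapply(seq_len(n_frames), function(i)
    if (i >= at) rigid2d(dx_mm, dy_mm, theta_deg) else rigid2d())
  motion_schedule(tfs, labels = ifelse(seq_len(n_frames) >= at, "moved",
                                       "baseline"))
}

# Smooth half-sine bump over n frames peaking exactly at `peak`.
bump <- function(n, peak) peak * sin(pi * (seq_len(n) - 1) / max(n - 1, 1))^2

#' Segmented session schedule with exact programmed maxima
#'
#' Emulates a coached motion session (e.g. limb motion, gentle and forceful
#' head motion): within each segment every DOF follows a smooth excursion
#' from baseline whose maximum absolute value equals the programmed maximum
#' exactly, so per-segment summaries have a known ground truth.
#'
#' @param segments data frame with columns `label`, `n_frames`, and per-DOF
#'   maxima: `dx_mm`, `dy_mm`, `theta_deg` (2D) or `lat_mm`, `ap_mm`,
#'   `si_mm`, `roll_deg`, `pitch_deg`, `yaw_deg` (3D).
#' @param dims `2` or `3`.
#' @param seed seed controlling the random sign of each excursion.
#' @return A `motion_schedule`.
#' @export
schedule_session <- function(segments, dims = 2, seed = NULL) {
  cols <- if (dims == 2) c("dx_mm", "dy_mm", "theta_deg")
          else c("lat_mm", "ap_mm", "si_mm", "roll_deg", "pitch_deg",
                 "yaw_deg")
  stopifnot(all(c("label", "n_frames", cols) %in% names(segments)))
  signs <- with_seed(seed,
    matrix(sample(c(-1, 1), nrow(segments) * length(cols), replace = TRUE),
           nrow(segments)))
  tfs <- list(); labs <- character(0)
  for (s in seq_len(nrow(segments))) {
    n <- segments$n_frames[s]
    curves <- vapply(seq_along(cols), function(j)
      bump(n, signs[s, j] * segments[[cols[j]]][s]), numeric(n))
    curves <- matrix(curves, nrow = n)
    for (i in seq_len(n)) {
      v <- curves[i, ]
      tfs[[length(tfs) + 1]] <-
        if (dims == 2) rigid2d(v[1], v[2], v[3])
        else rigid3d(v[1], v[2], v[3], v[4], v[5], v[6])
    }
    labs <- c(labs, rep(segments$label[s], n))
  }
  motion_schedule(tfs, labs)
}

#' Project a 3D motion schedule onto an orthogonal imaging plane
#'
#' Maps the in-plane components of each 6-DOF transform to the 2D transform
#' observed in that plane: axial sees (lateral, AP, yaw); sagittal sees
#' (AP, SI, pitch); coronal sees (lateral, SI, roll). Exact when the motion
#' is within the plane; a small-angle approximation otherwise.
#'
#' @param schedule a `motion_schedule` of [rigid3d].
#' @param plane `"axial"`, `"sagittal"`, or `"coronal"`.
#' @return A `motion_schedule` of [rigid2d].
#' @export
project_schedule <- function(schedule, plane) {
  plane <- match.arg(plane, c("axial", "sagittal", "coronal"))
  tfs <- lapply(schedule$transforms, function(tf) {
    stopifnot(inherits(tf, "rigid3d"))
    switch(plane,
      axial = rigid2d(tf$lat_mm, tf$ap_mm, tf$yaw_deg),
      sagittal = rigid2d(tf$ap_mm, tf$si_mm, tf$pitch_deg),
      coronal = rigid2d(tf$lat_mm, tf$si_mm, tf$roll_deg))
  })
  motion_schedule(tfs, schedule$labels)
}

#' Generate a planar cine sequence with ground-truth motion
#'
#' Frame i is the noiseless head slice moved by `schedule[i]` (bilinear
#' resampling about the head center), with MR-like noise added per frame and
#' optional crossline artifacts — full rows/columns with intensity scaled by
#' a constant factor, emulating the signature of interleaved orthogonal-plane
#' acquisition. An optional constant-intensity system border can be appended
#' (removed again by [crop_system_boundary()]).
#'
#' @param spec a [phantom_spec].
#' @param plane plane label.
#' @param schedule a `motion_schedule` of [rigid2d]; its length sets the
#'   frame count.
#' @param crossline `NULL` or list with elements `axis` ("row"/"col"),
#'   `index` (line index, `NULL` = random within the head), `factor`
#'   (intensity scale, default 1.5), `frames` (indices, `NULL` = all).
#' @param fps frame-rate preset (0.5 three-plane, 0.9 two-plane, 1.8--2
#'   single-plane).
#' @param noise_sd per-frame noise SD (0 = noiseless).
#' @param border_px,border_value constant system border appended around each
#'   frame.
#' @param seed RNG seed.
#' @return A [cine_sequence] with attributes `ground_truth` (the schedule),
#'   `masks` (tissue masks of the reference frame, pre-border),
#'   `crossline_truth` (data frame of injected lines), `border_px`.
#' @export
make_cine <- function(spec = phantom_spec(), plane = "axial",
                      schedule = schedule_static(10), crossline = NULL,
                      fps = 0.5, noise_sd = spec$noise_sd, border_px = 0,
                      border_value = 0, seed = NULL) {
  base <- make_head_slice(spec, plane, noise_sd = 0)
  n <- length(schedule)
  ctr <- base$center_mm
  cl_truth <- data.frame(frame = integer(0), axis = character(0),
                         index = integer(0))
  frames <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tf <- schedule$transforms[[i]]
      tf <- rigid2d(tf$dx_mm, tf$dy_mm, tf$theta_deg, center_mm = ctr)
      img <- if (tf$dx_mm == 0 && tf$dy_mm == 0 && tf$theta_deg == 0)
        base$image else apply_rigid_2d(base$image, tf)
      px <- add_mr_noise(img$pixels, noise_sd)
      if (!is.null(crossline)) {
        frames_hit <- if (is.null(crossline$frames)) seq_len(n)
                      else crossline$frames
        if (i %in% frames_hit) {
          axis <- match.arg(crossline$axis, c("row", "col"))
          fac <- if (is.null(crossline$factor)) 1.5 else crossline$factor
          idx <- crossline$index
          if (is.null(idx)) {
            rng <- if (axis == "row") range(which(rowSums(base$head$mask) > 0))
                   else range(which(colSums(base$head$mask) > 0))
            idx <- sample(seq(rng[1], rng[2]), 1)
          }
          if (axis == "row") px[idx, ] <- px[idx, ] * fac
          else px[, idx] <- px[, idx] * fac
          cl_truth <<- rbind(cl_truth,
                             data.frame(frame = i, axis = axis, index = idx))
        }
      }
      if (border_px > 0) {
        padded <- matrix(border_value, nrow(px) + 2 * border_px,
                         ncol(px) + 2 * border_px)
        padded[border_px + seq_len(nrow(px)),
               border_px + seq_len(ncol(px))] <- px
        px <- padded
      }
      planar_image(px, spec$spacing_mm, plane)
    })
  })
  # anatomy must stay inside the frame: reject schedules pushing the skull out
  ext <- c(spec$skull_semiaxes_mm[1] + max(abs(vapply(schedule$transforms,
           function(t) t$dx_mm, numeric(1)))),
           spec$skull_semiaxes_mm[2] + max(abs(vapply(schedule$transforms,
           function(t) t$dy_mm, numeric(1)))))
  half <- c((spec$n_col - 1) / 2, (spec$n_row - 1) / 2) * spec$spacing_mm
  if (any(ext > half))
    stop("make_cine: schedule moves anatomy outside the frame")
  seq <- cine_sequence(frames, fps)
  attr(seq, "ground_truth") <- schedule
  attr(seq, "masks") <- base[c("head", "skull", "brain", "ventricles")]
  attr(seq, "crossline_truth") <- cl_truth
  attr(seq, "border_px") <- border_px
  seq
}

#' Head phantom volume specification
#'
#' @param n_x,n_y,n_z volume size in voxels.
#' @param spacing_mm isotropic voxel size, mm.
#' @param skull_semiaxes_mm outer skull ellipsoid semi-axes (lat, AP, SI).
#' @param skull_thickness_mm shell thickness.
#' @param ventricle_semiaxes_mm ventricle ellipsoid semi-axes.
#' @param ventricle_offset_mm lateral offset of each ventricle from midline.
#' @param intensities named intensity levels.
#' @param noise_sd noise SD.
#' @return A `phantom_spec3d` list.
#' @export
phantom_spec3d <- function(n_x = 64, n_y = 64, n_z = 48, spacing_mm = 3,
                           skull_semiaxes_mm = c(65, 80, 60),
                           skull_thickness_mm = 7,
                           ventricle_semiaxes_mm = c(7, 18, 14),
                           ventricle_offset_mm = 13,
                           intensities = c(background = 0, brain = 120,
                                           skull = 200, ventricle = 40),
                           noise_sd = 4) {
  inner <- skull_semiaxes_mm - skull_thickness_mm
  if (any(inner <= 0)) stop("phantom_spec3d: skull geometry must be positive")
  if (ventricle_offset_mm + ventricle_semiaxes_mm[1] >= inner[1])
    stop("phantom_spec3d: ventricles must nest inside the brain")
  structure(list(n_x = n_x, n_y = n_y, n_z = n_z, spacing_mm = spacing_mm,
                 skull_semiaxes_mm = skull_semiaxes_mm,
                 skull_thickness_mm = skull_thickness_mm,
                 ventricle_semiaxes_mm = ventricle_semiaxes_mm,
                 ventricle_offset_mm = ventricle_offset_mm,
                 intensities = intensities, noise_sd = noise_sd),
            class = "phantom_spec3d")
}

ellipsoid_mask <- function(dims, spacing, center_mm, semi_mm) {
  x <- (seq_len(dims[1]) - 1) * spacing
  y <- (seq_len(dims[2]) - 1) * spacing
  z <- (seq_len(dims[3]) - 1) * spacing
  ((outer(outer((x - center_mm[1])^2 / semi_mm[1]^2,
                (y - center_mm[2])^2 / semi_mm[2]^2, "+"),
          (z - center_mm[3])^2 / semi_mm[3]^2, "+")) <= 1)
}

#' Generate a synthetic head volume with ground-truth tissue masks
#'
#' @param spec a [phantom_spec3d].
#' @param noise_sd override noise SD.
#' @param seed RNG seed.
#' @return List: `volume` ([volume_image], MR), masks `head`, `brain`,
#'   `ventricles` ([mask_roi]), and `center_mm`.
#' @export
make_head_volume <- function(spec = phantom_spec3d(),
                             noise_sd = spec$noise_sd, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec3d"))
  d <- c(spec$n_x, spec$n_y, spec$n_z)
  sp <- spec$spacing_mm
  ctr <- (d - 1) / 2 * sp
  outer_m <- ellipsoid_mask(d, sp, ctr, spec$skull_semiaxes_mm)
  inner_m <- ellipsoid_mask(d, sp, ctr,
                            spec$skull_semiaxes_mm - spec$skull_thickness_mm)
  v1 <- ellipsoid_mask(d, sp, ctr + c(-spec$ventricle_offset_mm, 0, 0),
                       spec$ventricle_semiaxes_mm)
  v2 <- ellipsoid_mask(d, sp, ctr + c(spec$ventricle_offset_mm, 0, 0),
                       spec$ventricle_semiaxes_mm)
  vent <- (v1 | v2) & inner_m
  iv <- spec$intensities
  vox <- array(iv[["background"]], d)
  vox[outer_m] <- iv[["skull"]]
  vox[inner_m] <- iv[["brain"]]
  vox[vent] <- iv[["ventricle"]]
  if (noise_sd > 0) {
    vox <- with_seed(seed, array(add_mr_noise(vox, noise_sd), d))
  }
  list(volume = volume_image(vox, sp, "MR"),
       head = mask_roi(outer_m, "head"),
       brain = mask_roi(inner_m & !vent, "brain"),
       ventricles = mask_roi(vent, "ventricles"),
       center_mm = ctr)
}

#' Generate a uniform QA phantom slice
#'
#' A disk emulating the 170 mm spherical head phantom's central slice, with
#' optional multiplicative nonuniformity (linear gradient hitting exact
#' intensity extremes) and phase-direction ghost replicas (shifted by half
#' the field of view along rows, wrapped), for exercising the uniformity,
#' SNR and ghosting metrics.
#'
#' @param diameter_mm phantom diameter.
#' @param signal in-disk intensity.
#' @param noise_sd channel noise SD (Rician/Rayleigh model).
#' @param ghost_fraction intensity of the ghost replica relative to the
#'   disk (>= 0).
#' @param nonuniformity `NULL`, or `c(low, high)` intensity extremes that
#'   the in-disk gradient attains exactly.
#' @param spacing_mm pixel size.
#' @param n_px image side length in pixels (default fits the disk with a
#'   margin).
#' @param seed RNG seed.
#' @return List: `image` ([planar_image]), `disk` ([mask_roi]).
#' @export
make_uniform_phantom <- function(diameter_mm = 170, signal = 200,
                                 noise_sd = 0, ghost_fraction = 0,
                                 nonuniformity = NULL, spacing_mm = 1,
                                 n_px = NULL, seed = NULL) {
  if (ghost_fraction < 0)
    stop("make_uniform_phantom: ghost_fraction must be >= 0")
  if (is.null(n_px)) n_px <- ceiling(diameter_mm / spacing_mm * 1.4)
  if (diameter_mm > (n_px - 1) * spacing_mm)
    stop("make_uniform_phantom: diameter does not fit the image")
  ctr <- rep((n_px - 1) / 2 * spacing_mm, 2)
  disk <- ellipse_mask(n_px, n_px, spacing_mm, ctr, rep(diameter_mm / 2, 2))
  px <- matrix(0, n_px, n_px)
  px[disk] <- signal
  if (!is.null(nonuniformity)) {
    stopifnot(length(nonuniformity) == 2, nonuniformity[1] <= nonuniformity[2])
    cols <- col(px)[disk]
    f <- (cols - min(cols)) / (max(cols) - min(cols))
    px[disk] <- nonuniformity[1] + f * (nonuniformity[2] - nonuniformity[1])
  }
  if (ghost_fraction > 0) {
    shift <- floor(n_px / 2)
    idx <- ((seq_len(n_px) - 1 + shift) %% n_px) + 1
    px <- px + ghost_fraction * px[idx, ]
  }
  if (noise_sd > 0) px <- with_seed(seed, add_mr_noise(px, noise_sd))
  list(image = planar_image(px, spacing_mm, "axial"),
       disk = mask_roi(disk, "phantom"))
}

#' Generate a low-contrast-object phantom slice
#'
#' An ACR-style slice: a uniform background disk bearing 10 radial spokes of
#' three circles each; circle intensity = background + the spoke's contrast.
#' The returned template gives every circle's center and radius for the
#' automated detectability count.
#'
#' @param contrasts numeric length-10, contrast of each spoke's circles
#'   above background.
#' @param noise_sd channel noise SD.
#' @param background background disk intensity.
#' @param spacing_mm pixel size.
#' @param seed RNG seed.
#' @return List: `image` ([planar_image]), `template` (data frame with
#'   `spoke`, `circle`, `row`, `col`, `radius_px`), `disk` ([mask_roi]).
#' @export
make_low_contrast_slice <- function(contrasts, noise_sd = 0,
                                    background = 100, spacing_mm = 1,
                                    seed = NULL) {
  if (length(contrasts) != 10)
    stop("make_low_contrast_slice: exactly 10 spoke contrasts required")
  n_px <- 200
  ctr_px <- (n_px + 1) / 2
  disk_r_mm <- 90
  ctr_mm <- rep((n_px - 1) / 2 * spacing_mm, 2)
  disk <- ellipse_mask(n_px, n_px, spacing_mm, ctr_mm, rep(disk_r_mm, 2))
  px <- matrix(0, n_px, n_px)
  px[disk] <- background
  radii_mm <- c(30, 52, 74)     # circle centers' radial positions
  circ_r_mm <- c(7, 5.5, 4)     # circle radii, outer circles smaller
  template <- expand.grid(circle = 1:3, spoke = 1:10)[, c("spoke", "circle")]
  template$row <- template$col <- template$radius_px <- NA_real_
  k <- 0
  for (s in 1:10) {
    ang <- (s - 1) * 2 * pi / 10 - pi / 2
    for (ci in 1:3) {
      k <- k + 1
      cx <- ctr_mm[1] + radii_mm[ci] * cos(ang)
      cy <- ctr_mm[2] + radii_mm[ci] * sin(ang)
      m <- ellipse_mask(n_px, n_px, spacing_mm, c(cx, cy),
                        rep(circ_r_mm[ci], 2))
      px[m] <- background + contrasts[s]
      template$row[k] <- cy / spacing_mm + 1
      template$col[k] <- cx / spacing_mm + 1
      template$radius_px[k] <- circ_r_mm[ci] / spacing_mm
    }
  }
  if (noise_sd > 0) px <- with_seed(seed, add_mr_noise(px, noise_sd))
  list(image = planar_image(px, spacing_mm, "axial"), template = template,
       disk = mask_roi(disk, "phantom"))
}
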