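# Shared fixtures and independent oracles. The oracles deliberately avoid the
# package's compiled samplers: plain-R bilinear interpolation and exhaustive
# grid search, so that registration results can be cross-checked against an
# implementation-independent path.

with_seed_test <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Compact head spec: keeps per-frame cost low in the unit tests.
small_spec <- function(noise_sd = 4) {
  phantom_spec(n_row = 120, n_col = 120, spacing_mm = 1.3,
               skull_semiaxes_mm = c(48, 60), skull_thickness_mm = 6,
               ventricle_semiaxes_mm = c(5, 14), ventricle_offset_mm = 10,
               noise_sd = noise_sd)
}

tiny_spec <- function(noise_sd = 0) {
  phantom_spec(n_row = 64, n_col = 64, spacing_mm = 1.3,
               skull_semiaxes_mm = c(26, 32), skull_thickness_mm = 5,
               ventricle_semiaxes_mm = c(3, 8), ventricle_offset_mm = 7,
               noise_sd = noise_sd)
}

small_spec3d <- function(noise_sd = 4) phantom_spec3d(noise_sd = noise_sd)

# Independent bilinear sampler on 0-based fractional indices; NA outside.
bilin_r <- function(px, fr, fc) {
  nr <- nrow(px); nc <- ncol(px)
  valid <- fr >= 0 & fc >= 0 & fr <= nr - 1 & fc <= nc - 1
  r0 <- pmax(pmin(floor(fr), nr - 2), 0)
  c0 <- pmax(pmin(floor(fc), nc - 2), 0)
  ar <- fr - r0; ac <- fc - c0
  v <- px[cbind(r0 + 1, c0 + 1)] * (1 - ar) * (1 - ac) +
    px[cbind(r0 + 2, c0 + 1)] * ar * (1 - ac) +
    px[cbind(r0 + 1, c0 + 2)] * (1 - ar) * ac +
    px[cbind(r0 + 2, c0 + 2)] * ar * ac
  v[!valid] <- NA
  v
}

# Exhaustive grid-search oracle for rigid 2D registration: scores every
# (dx, dy, theta) candidate by Pearson correlation of the reference ROI
# values against moving-image samples at forward-transformed locations,
# with the same smallest-transform tie-break the package documents.
oracle_register2d <- function(ref, moving, roi, center_mm, dxs, dys, thetas) {
  idx <- which(roi$mask, arr.ind = TRUE)
  sp <- ref$spacing_mm
  px <- (idx[, 2] - 1) * sp[2]
  py <- (idx[, 1] - 1) * sp[1]
  rv <- ref$pixels[idx]
  best <- NULL
  best_score <- -Inf
  for (th in thetas) for (dy in dys) for (dx in dxs) {
    a <- th * pi / 180
    ux <- px - center_mm[1]; uy <- py - center_mm[2]
    tx <- cos(a) * ux - sin(a) * uy + center_mm[1] + dx
    ty <- sin(a) * ux + cos(a) * uy + center_mm[2] + dy
    mv <- bilin_r(moving$pixels, ty / sp[1], tx / sp[2])
    ok <- !is.na(mv)
    if (sum(ok) < max(10, floor(0.5 * length(rv)))) next
    s <- suppressWarnings(stats::cor(rv[ok], mv[ok]))
    if (is.na(s)) next
    better <- s > best_score + 1e-12
    tie <- abs(s - best_score) <= 1e-12 && !is.null(best) &&
      (abs(th) < abs(best[3]) - 1e-12 ||
         (abs(abs(th) - abs(best[3])) <= 1e-12 &&
            abs(dx) + abs(dy) < abs(best[1]) + abs(best[2]) - 1e-12))
    if (better || tie) {
      best <- c(dx, dy, th)
      best_score <- s
    }
  }
  list(dx = best[1], dy = best[2], theta = best[3], score = best_score)
}

# Integer-shift cross-correlation oracle: best (drow, dcol) alignment of two
# frames over +/- max_shift pixels.
oracle_int_shift <- function(a, b, max_shift = 6) {
  d <- dim(a)
  best <- c(0, 0); best_s <- -Inf
  for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
    r1 <- max(1, 1 + dr):min(d[1], d[1] + dr)
    c1 <- max(1, 1 + dc):min(d[2], d[2] + dc)
    s <- stats::cor(as.vector(b[r1, c1]),
                    as.vector(a[r1 - dr, c1 - dc]))
    if (!is.na(s) && s > best_s) { best_s <- s; best <- c(dr, dc) }
  }
  best  # (row shift, col shift) of b relative to a
}

make_disk_image <- function(n = 80, radius_px = 20, value = 200, bg = 10,
                            spacing = 1, center = NULL) {
  if (is.null(center)) center <- rep((n + 1) / 2, 2)
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  px <- matrix(bg, n, n)
  px[(rr - center[1])^2 + (cc - center[2])^2 <= radius_px^2] <- value
  planar_image(px, spacing)
}

# ring of ~1 px thickness at the given radius
make_ring_mask <- function(n = 80, radius_px = 20, center = NULL) {
  if (is.null(center)) center <- rep((n + 1) / 2, 2)
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  mask_roi(abs(d - radius_px) <= 0.5, "ring")
}

# 6-neighborhood erosion of a 3D logical array (independent of EBImage)
erode6 <- function(m) {
  d <- dim(m)
  out <- m
  sh <- function(a, ax, k) {
    i <- pmin(pmax(seq_len(d[ax]) + k, 1), d[ax])
    switch(ax, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  for (ax in 1:3) out <- out & sh(m, ax, -1) & sh(m, ax, 1)
  out
}

table6_df <- function() {
  read.csv(system.file("extdata", "table6_doses.csv", package = "mrgqa"))
}
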