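test_that("head slice tissues are strictly nested and noiseless levels exact", {
  hs <- make_head_slice(phantom_spec(), noise_sd = 0)
  vent <- hs$ventricles$mask
  brain <- hs$brain$mask | vent
  head <- hs$head$mask
  expect_true(all(head[vent]))
  expect_true(all(head[brain]))
  expect_true(sum(vent) < sum(brain) && sum(brain) < sum(head))
  expect_false(any(vent & hs$skull$mask))
  expect_setequal(unique(as.vector(hs$image$pixels)), c(0, 40, 120, 200))
  expect_error(phantom_spec(ventricle_offset_mm = 70), "nest")
})

test_that("pixel grid has the expected physical extent", {
  spec <- phantom_spec(n_row = 192, n_col = 192, spacing_mm = 1.3)
  hs <- make_head_slice(spec, noise_sd = 0)
  expect_equal(dim(hs$image$pixels) * hs$image$spacing_mm, c(249.6, 249.6))
})

test_that("generators are bit-identical under a fixed seed", {
  s1 <- make_cine(small_spec(), schedule = schedule_static(3), seed = 42)
  s2 <- make_cine(small_spec(), schedule = schedule_static(3), seed = 42)
  s3 <- make_cine(small_spec(), schedule = schedule_static(3), seed = 43)
  for (i in 1:3)
    expect_identical(s1$frames[[i]]$pixels, s2$frames[[i]]$pixels)
  expect_false(identical(s1$frames[[1]]$pixels, s3$frames[[1]]$pixels))
})

test_that("identity schedule with zero noise yields identical frames", {
  s <- make_cine(small_spec(), schedule = schedule_static(4), noise_sd = 0)
  for (i in 2:4)
    expect_identical(s$frames[[i]]$pixels, s$frames[[1]]$pixels)
})

test_that("a programmed step shows up at the cross-correlation oracle shift", {
  spec <- small_spec()
  s <- make_cine(spec, schedule = schedule_step(3, at = 2, dx_mm = 5.2),
                 noise_sd = 0)
  shift <- oracle_int_shift(s$frames[[1]]$pixels, s$frames[[2]]$pixels)
  expect_equal(shift[2], round(5.2 / spec$spacing_mm))  # column shift
  expect_equal(shift[1], 0)
})

test_that("fps presets set the timestamp spacing", {
  s <- make_cine(small_spec(), schedule = schedule_static(4), fps = 0.5)
  expect_equal(diff(s$timestamps), rep(2, 3))  # 3-plane preset: 2 s apart
  s <- make_cine(small_spec(), schedule = schedule_static(4), fps = 2)
  expect_equal(diff(s$timestamps), rep(0.5, 3))
})

test_that("session schedules hit the programmed per-segment maxima exactly", {
  segs <- data.frame(label = c("gentle", "forceful"), n_frames = c(9, 9),
                     dx_mm = c(2.2, 6.3), dy_mm = c(1.1, 5.8),
                     theta_deg = c(1.0, 2.0))
  sch <- schedule_session(segs, dims = 2, seed = 7)
  expect_length(sch, 18)
  for (s in 1:2) {
    rows <- which(sch$labels == segs$label[s])
    expect_equal(max(abs(vapply(sch$transforms[rows], `[[`, 0, "dx_mm"))),
                 segs$dx_mm[s])
    expect_equal(max(abs(vapply(sch$transforms[rows], `[[`, 0, "theta_deg"))),
                 segs$theta_deg[s])
  }
})

test_that("3D rigid resampling inverts within interpolation tolerance", {
  hv <- make_head_volume(small_spec3d(), noise_sd = 0)
  tf <- rigid3d(4, -3, 5, 2, -1.5, 2.5)
  fwd <- apply_rigid_3d(hv$volume, tf)
  back <- apply_rigid_3d(fwd, invert_rigid(tf))
  err <- abs(back$voxels - hv$volume$voxels)
  rng <- diff(range(hv$volume$voxels))
  # trilinear interpolation cannot reproduce the unresolved tissue steps of
  # the piecewise-constant phantom at the interfaces themselves; away from
  # them the double resampling is well under 2% of the dynamic range
  core <- erode6(erode6(hv$brain$mask))
  expect_gt(sum(core), 1e4)
  expect_lte(max(err[core]), 0.02 * rng)
  expect_lte(median(err[hv$brain$mask]), 0.02 * rng)
})

test_that("central slices of an in-plane-transformed volume match 2D resampling", {
  hv <- make_head_volume(small_spec3d(), noise_sd = 0)
  d <- dim(hv$volume$voxels)
  kz <- (d[3] + 1) / 2  # central axial slice index (odd grid assumed below)
  kz <- floor(kz)
  tf3 <- rigid3d(lat_mm = 3, ap_mm = -2, yaw_deg = 2)
  mv <- apply_rigid_3d(hv$volume, tf3)
  # the same motion applied in 2D to the original central slice; the axial
  # planar view has rows = AP and cols = lateral, i.e. the transpose of the
  # volume's [lat, AP] slice
  sl <- planar_image(t(hv$volume$voxels[, , kz]), hv$volume$spacing_mm[1:2])
  ctr <- (d[1:2] - 1) / 2 * hv$volume$spacing_mm[1:2]
  sl2 <- apply_rigid_2d(sl, rigid2d(3, -2, 2, center_mm = ctr))
  a <- t(mv$voxels[, , kz])
  b <- sl2$pixels
  inside <- b > 0 & a > 0
  expect_gt(stats::cor(a[inside], b[inside]), 0.999)
  expect_lte(median(abs(a[inside] - b[inside])),
             0.01 * diff(range(b)))
})

test_that("uniform phantom: ideal disk gives PIU ~ 100 and ghosting ~ 0", {
  ph <- make_uniform_phantom(diameter_mm = 170, signal = 200)
  st <- roi_stats(ph$image, ph$disk)
  expect_equal(percent_uniformity(st), 100)
  expect_equal(piu(st$min, st$max), 100)
  # symmetric field: ghosting ratio from four symmetric edge ROIs is 0
  expect_equal(ghosting_ratio(10, 10, 10, 10, st$mean), 0)
})

test_that("uniform phantom nonuniformity hits exact intensity extremes", {
  ph <- make_uniform_phantom(nonuniformity = c(702.75, 759.16))
  st <- roi_stats(ph$image, ph$disk)
  expect_equal(st$min, 702.75)
  expect_equal(st$max, 759.16)
  expect_equal(piu(st$min, st$max), 96.1)
})

test_that("ghost replicas raise the measured ghosting ratio monotonically", {
  ratios <- vapply(c(0, 0.01, 0.03, 0.06), function(g) {
    ph <- make_uniform_phantom(diameter_mm = 100, signal = 500, n_px = 160,
                               ghost_fraction = g)
    px <- ph$image$pixels
    # edge ROIs: strips outside the disk at top/bottom (phase) and sides
    n <- nrow(px)
    top <- mean(px[1:10, 60:100]); bottom <- mean(px[(n - 9):n, 60:100])
    left <- mean(px[60:100, 1:10]); right <- mean(px[60:100, (n - 9):n])
    ghosting_ratio(top, bottom, left, right,
                   roi_stats(ph$image, ph$disk)$mean, digits = NA)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_error(make_uniform_phantom(ghost_fraction = -0.1), "ghost_fraction")
})

test_that("low-contrast slice respects its template ground truth", {
  lc <- make_low_contrast_slice(contrasts = rep(50, 10))
  expect_equal(nrow(lc$template), 30)
  expect_equal(low_contrast_count(lc$image, lc$template), 10L)
  expect_error(make_low_contrast_slice(contrasts = rep(50, 9)), "10")
})

test_that("cine ground truth equals the transforms actually applied", {
  # noiseless frames registered by the independent exhaustive oracle recover
  # the stored schedule (no hidden resampling offsets)
  spec <- tiny_spec()
  sch <- schedule_step(2, at = 2, dx_mm = 1.3, dy_mm = -2.6)
  s <- make_cine(spec, schedule = sch, noise_sd = 0)
  hs <- make_head_slice(spec, noise_sd = 0)
  cs <- detect_contours(s$frames[[1]])
  roi <- build_registration_roi(cs$target_filled, NULL, spec$spacing_mm,
                                c(outer_mm = 2, inner_mm = 6))
  o <- oracle_register2d(s$frames[[1]], s$frames[[2]], roi, hs$center_mm,
                         dxs = seq(-2.6, 2.6, by = 1.3),
                         dys = seq(-2.6, 2.6, by = 1.3), thetas = 0)
  expect_equal(o$dx, 1.3)
  expect_equal(o$dy, -2.6)
})

test_that("schedules that move anatomy off-frame are rejected", {
  expect_error(
    make_cine(tiny_spec(), schedule = schedule_step(2, 2, dx_mm = 30),
              noise_sd = 0),
    "outside the frame")
})
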