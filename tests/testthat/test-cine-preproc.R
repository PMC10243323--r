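test_that("fixed-margin cropping removes the stated border", {
  frames <- lapply(1:2, function(i)
    planar_image(matrix(rnorm(200 * 200), 200), c(1, 1)))
  seq <- cine_sequence(frames, 1)
  out <- crop_system_boundary(seq, margin = 10)
  expect_equal(dim(out$frames[[1]]$pixels), c(180, 180))
  expect_equal(out$frames[[1]]$spacing_mm, c(1, 1))
  expect_equal(out$frames[[1]]$pixels, frames[[1]]$pixels[11:190, 11:190])
  # zero margin is the identity
  same <- crop_system_boundary(seq, margin = 0)
  expect_equal(same$frames[[1]]$pixels, frames[[1]]$pixels)
  expect_error(crop_system_boundary(seq, margin = 100), "crop window")
})

test_that("auto-crop removes exactly the generator's constant border", {
  spec <- small_spec()
  s <- make_cine(spec, schedule = schedule_static(3), border_px = 7,
                 border_value = 0, noise_sd = 4, seed = 5)
  out <- crop_system_boundary(s, "auto")
  expect_equal(attr(out, "crop_margin_px"), rep(7L, 4))
  expect_equal(dim(out$frames[[1]]$pixels), c(spec$n_row, spec$n_col))
  # borderless noisy frames are left untouched
  s2 <- make_cine(spec, schedule = schedule_static(2), noise_sd = 4, seed = 5)
  expect_equal(attr(crop_system_boundary(s2, "auto"), "crop_margin_px"),
               rep(0L, 4))
})

test_that("contour detection localizes a bright disk to sub-pixel accuracy", {
  img <- make_disk_image(n = 80, radius_px = 20, value = 200, bg = 10)
  cs <- detect_contours(img, config = list(gating_margin_mm = 3))
  ctr <- cs$rotation_center_px
  expect_lt(max(abs(ctr - c(40.5, 40.5))), 0.5)
  out <- which(cs$target_outline$mask, arr.ind = TRUE)
  radii <- sqrt((out[, 1] - 40.5)^2 + (out[, 2] - 40.5)^2)
  # 1-px outline of the rasterized circle: within ~1 px of the radius, with
  # an extra half-pixel inward from the diagonal staircase
  expect_true(all(radii >= 18.5 & radii <= 21))
  # gating boundary is the target expanded by the margin
  expect_true(all(cs$target_filled$mask[cs$boundary_filled$mask == FALSE] == FALSE))
  expect_gt(sum(cs$boundary_filled$mask), sum(cs$target_filled$mask))
})

test_that("contour detection errors on a blank frame", {
  expect_error(detect_contours(planar_image(matrix(7, 40, 40))), "contrast")
})

test_that("contour detection picks the largest of two components", {
  px <- matrix(0, 100, 100)
  rr <- row(px); cc <- col(px)
  px[(rr - 30)^2 + (cc - 30)^2 <= 15^2] <- 200  # large disk
  px[(rr - 75)^2 + (cc - 75)^2 <= 7^2] <- 200   # small disk
  cs <- detect_contours(planar_image(px), config = list(select = "largest"))
  expect_lt(max(abs(cs$rotation_center_px - c(30, 30))), 1)
})

test_that("contour filling recovers the analytic disk area and center", {
  ring <- make_ring_mask(n = 80, radius_px = 20)
  fc <- fill_contour(ring)
  # analytic pixel count of the disk bounded by the ring's outer edge
  rr <- row(matrix(0, 80, 80)); cc <- col(matrix(0, 80, 80))
  analytic <- sum((rr - 40.5)^2 + (cc - 40.5)^2 <= 20.5^2)
  expect_lt(abs(sum(fc$filled$mask) - analytic) / analytic, 0.02)
  expect_lt(max(abs(fc$rotation_center - c(40.5, 40.5))), 0.5)
})

test_that("contour filling is idempotent on an already-filled mask", {
  disk <- make_disk_image(n = 60, radius_px = 15, value = 1, bg = 0)
  filled <- mask_roi(disk$pixels > 0)
  fc <- fill_contour(filled)
  expect_equal(fc$filled$mask, filled$mask)
})

test_that("contour filling closes small gaps but rejects open curves", {
  ring <- make_ring_mask(n = 80, radius_px = 20)
  gap <- ring$mask
  gap[40:41, which(gap[40, ])[1]] <- FALSE  # 1-px notch
  fc <- fill_contour(mask_roi(gap), dilate_radius_px = 2)
  expect_gt(sum(fc$filled$mask), 0.9 * pi * 20^2)
  # an open arc cannot be closed
  arc <- ring$mask
  arc[, 1:40] <- FALSE
  expect_error(fill_contour(mask_roi(arc)), "open")
})

test_that("inpainting restores a constant field exactly and a ramp closely", {
  const <- planar_image(matrix(100, 50, 50))
  ov <- matrix(FALSE, 50, 50); ov[20:30, 10:40] <- TRUE
  out <- inpaint_overlay(const, mask_roi(ov))
  expect_equal(out$pixels, const$pixels)
  # horizontal ramp with a thin vertical overlay line
  ramp <- planar_image(matrix(rep(1:60, each = 60), 60, 60))
  ovl <- matrix(FALSE, 60, 60); ovl[, 30] <- TRUE
  got <- inpaint_overlay(ramp, mask_roi(ovl))
  expect_lte(max(abs(got$pixels - ramp$pixels)), 1)
  expect_equal(got$pixels[, -30], ramp$pixels[, -30])  # untouched elsewhere
})

test_that("inpainting validates its overlay", {
  img <- planar_image(matrix(rnorm(100), 10))
  expect_identical(inpaint_overlay(img, mask_roi(matrix(FALSE, 10, 10))), img)
  expect_error(inpaint_overlay(img, mask_roi(matrix(TRUE, 10, 10))),
               "whole frame")
})

test_that("crossline detection flags injected lines and nothing else", {
  spec <- small_spec()
  # uniform frame: nothing to flag
  u <- planar_image(matrix(80, 60, 60))
  expect_length(detect_crosslines(u, "row")$indices, 0)
  # noiseless head slice with row 37 raised 50%: exactly {37} at k = 5
  hs <- make_head_slice(spec, noise_sd = 0)
  px <- hs$image$pixels
  px[37, ] <- px[37, ] * 1.5
  cl <- detect_crosslines(planar_image(px, spec$spacing_mm), "row", k = 5)
  expect_equal(cl$indices, 37L)
  expect_error(detect_crosslines(planar_image(matrix(1, 3, 9)), "row"),
               "at least 5")
})

test_that("two saturated columns are flagged with no false positives", {
  spec <- small_spec()
  for (r in 1:50) {
    px <- make_head_slice(spec, noise_sd = 4, seed = 500 + r)$image$pixels
    px[, 40] <- px[, 40] * 2
    px[, 85] <- px[, 85] * 2
    f <- planar_image(px, spec$spacing_mm)
    cols <- detect_crosslines(f, "col", k = 5)$indices
    rows <- detect_crosslines(f, "row", k = 5)$indices
    expect_setequal(cols, c(40L, 85L))
    expect_length(rows, 0)
  }
})

test_that("registration ROI is a skull-band annulus minus crossline lines", {
  disk <- make_disk_image(n = 90, radius_px = 25, value = 1, bg = 0,
                          spacing = 1)
  filled <- mask_roi(disk$pixels > 0)
  roi <- build_registration_roi(filled, NULL, c(1, 1),
                                c(outer_mm = 3, inner_mm = 6))
  idx <- which(roi$mask, arr.ind = TRUE)
  radii <- sqrt((idx[, 1] - 45.5)^2 + (idx[, 2] - 45.5)^2)
  expect_true(all(radii >= 25 - 6 - 1 & radii <= 25 + 3 + 1))
  # deep interior is excluded from the band
  expect_false(any(radii < 17))
  # a crossline row through the annulus is excluded
  cl <- structure(list(axis = "row", indices = 30L, strengths = 9),
                  class = "crossline_artifact")
  roi2 <- build_registration_roi(filled, cl, c(1, 1),
                                 c(outer_mm = 3, inner_mm = 6))
  expect_false(any(roi2$mask[30, ]))
  expect_true(any(roi$mask[30, ]))
  # crosslines covering the whole band leave nothing
  cl_all <- structure(list(axis = "row", indices = 1:90, strengths = rep(9, 90)),
                      class = "crossline_artifact")
  expect_error(build_registration_roi(filled, cl_all, c(1, 1)), "empty")
})

test_that("gating compares the current target against the boundary", {
  n <- 60
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  target <- mask_roi((rr - 30)^2 + (cc - 30)^2 <= 10^2)
  boundary <- mask_roi((rr - 30)^2 + (cc - 30)^2 <= 13^2)  # 3 px ~ 3 mm
  g <- gate_check(target, boundary)
  expect_true(g$beam_on)
  expect_equal(g$excursion_fraction, 0)
  # target equal to the boundary: still on at the limit
  g2 <- gate_check(boundary, boundary)
  expect_true(g2$beam_on)
  # shift beyond the 3 px expansion: beam off
  shifted <- mask_roi((rr - 30)^2 + (cc - 34)^2 <= 10^2)
  g3 <- gate_check(shifted, boundary)
  expect_false(g3$beam_on)
  expect_gt(g3$excursion_fraction, 0)
  expect_error(gate_check(mask_roi(matrix(FALSE, n, n)), boundary), "empty")
})
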