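test_that("pearson similarity matches the product-moment formula", {
  expect_equal(pearson_similarity(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5)), 1)
  expect_equal(pearson_similarity(c(3, 1, 4), -c(3, 1, 4)), -1)
  expect_equal(pearson_similarity(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_similarity(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_similarity(1:3, 1:4), "equal lengths")
})

test_that("self-registration returns the identity with score 1", {
  hs <- make_head_slice(small_spec(), noise_sd = 4, seed = 1)
  cs <- detect_contours(hs$image)
  roi <- build_registration_roi(cs$target_filled, NULL, hs$image$spacing_mm)
  r <- register_frame(hs$image, hs$image, roi)
  expect_equal(r$transform$dx_mm, 0)
  expect_equal(r$transform$dy_mm, 0)
  expect_equal(r$transform$theta_deg, 0)
  expect_equal(r$score, 1)
  expect_false(r$boundary_warning)
})

test_that("similarity is invariant to affine intensity rescaling", {
  spec <- small_spec()
  hs <- make_head_slice(spec, noise_sd = 4, seed = 2)
  tf <- rigid2d(2.6, -1.3, 1.5, center_mm = hs$center_mm)
  mv <- apply_rigid_2d(hs$image, tf)
  mv2 <- planar_image(1.7 * mv$pixels + 30, mv$spacing_mm)
  cs <- detect_contours(hs$image)
  roi <- build_registration_roi(cs$target_filled, NULL, spec$spacing_mm)
  r1 <- register_frame(hs$image, mv, roi, hs$center_mm)
  r2 <- register_frame(hs$image, mv2, roi, hs$center_mm)
  expect_equal(unlist(r1$transform[1:3]), unlist(r2$transform[1:3]))
  expect_equal(r1$score, r2$score, tolerance = 1e-9)
})

test_that("noiseless parameter recovery is sub-half-pixel and 0.1 degree", {
  spec <- small_spec()
  hs <- make_head_slice(spec, noise_sd = 0)
  cs <- detect_contours(hs$image)
  roi <- build_registration_roi(cs$target_filled, NULL, spec$spacing_mm)
  half_px <- 0.5 * spec$spacing_mm
  cases <- list(c(3.9, -2.6, 0), c(-2.6, 1.3, 1), c(2, 3, -3),
                c(0.9, -4, 5))
  for (tr in cases) {
    mv <- apply_rigid_2d(hs$image, rigid2d(tr[1], tr[2], tr[3],
                                           center_mm = hs$center_mm))
    r <- register_frame(hs$image, mv, roi, hs$center_mm)
    expect_lte(abs(r$transform$dx_mm - tr[1]), half_px)
    expect_lte(abs(r$transform$dy_mm - tr[2]), half_px)
    expect_lte(abs(r$transform$theta_deg - tr[3]), 0.1 + 1e-9)
  }
})

test_that("recovery at SNR 20 stays within one pixel and half a degree", {
  spec <- small_spec()
  hs <- make_head_slice(spec, noise_sd = 0)
  # channel noise so that brain SNR ~ 20: 120 * 0.66 / (0.655 * sd) = 20
  sd20 <- 120 * 0.66 / (20 * 0.655)
  base <- make_head_slice(spec, noise_sd = sd20, seed = 31)$image
  cs <- detect_contours(base)
  roi <- build_registration_roi(cs$target_filled, NULL, spec$spacing_mm)
  cases <- list(c(3.9, -2.6, 0), c(-1.3, 2.6, 2), c(4, 1, -4))
  for (i in seq_along(cases)) {
    tr <- cases[[i]]
    clean <- apply_rigid_2d(hs$image, rigid2d(tr[1], tr[2], tr[3],
                                              center_mm = hs$center_mm))
    mv <- planar_image(with_seed_test(40 + i,
                                      sqrt((clean$pixels +
                                              rnorm(length(clean$pixels), 0, sd20))^2 +
                                             rnorm(length(clean$pixels), 0, sd20)^2)),
                       spec$spacing_mm)
    r <- register_frame(base, mv, roi, hs$center_mm)
    expect_lte(abs(r$transform$dx_mm - tr[1]), spec$spacing_mm)
    expect_lte(abs(r$transform$dy_mm - tr[2]), spec$spacing_mm)
    expect_lte(abs(r$transform$theta_deg - tr[3]), 0.5)
  }
})

test_that("the optimizer agrees with the exhaustive grid-search oracle", {
  spec <- tiny_spec()
  hs <- make_head_slice(spec, noise_sd = 3, seed = 9)
  mv <- apply_rigid_2d(make_head_slice(spec, noise_sd = 0)$image,
                       rigid2d(1.2, -0.8, 1, center_mm = hs$center_mm))
  cs <- detect_contours(hs$image)
  roi <- build_registration_roi(cs$target_filled, NULL, spec$spacing_mm,
                                c(outer_mm = 2, inner_mm = 6))
  grid <- seq(-2.5, 2.5, by = 0.5)
  o <- oracle_register2d(hs$image, mv, roi, hs$center_mm,
                         dxs = grid, dys = grid, thetas = grid)
  r <- register_frame(hs$image, mv, roi, hs$center_mm,
                      search = search_config(range_mm = 2.5, range_deg = 2.5,
                                             coarse_step_mm = 0.5,
                                             coarse_step_deg = 0.5,
                                             levels = 1,
                                             max_points = Inf,
                                             smooth_sigma_px = 0))
  expect_equal(r$transform$dx_mm, o$dx)
  expect_equal(r$transform$dy_mm, o$dy)
  expect_equal(r$transform$theta_deg, o$theta)
  expect_equal(r$score, o$score, tolerance = 1e-9)
  # the hierarchical search can only do at least as well on its finer grid
  rh <- register_frame(hs$image, mv, roi, hs$center_mm,
                       search = search_config(range_mm = 2.5, range_deg = 2.5,
                                              coarse_step_mm = 0.5,
                                              coarse_step_deg = 0.5,
                                              levels = 3,
                                              max_points = Inf,
                                              smooth_sigma_px = 0))
  expect_gte(rh$score, o$score - 1e-9)
})

test_that("an optimum on the search boundary raises the truncation flag", {
  spec <- small_spec()
  hs <- make_head_slice(spec, noise_sd = 0)
  mv <- apply_rigid_2d(hs$image, rigid2d(6, 0, 0, center_mm = hs$center_mm))
  cs <- detect_contours(hs$image)
  roi <- build_registration_roi(cs$target_filled, NULL, spec$spacing_mm)
  r <- register_frame(hs$image, mv, roi, hs$center_mm,
                      search = search_config(range_mm = 5, range_deg = 2,
                                             coarse_step_mm = 2.5))
  expect_true(r$boundary_warning)
})
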