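test_that("ROI statistics are exact sample statistics", {
  img <- planar_image(matrix(100, 20, 20), c(1, 1))
  st <- roi_stats(img, mask_roi(matrix(TRUE, 20, 20)))
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)
  expect_equal(st$roi_area_cm2, 4)  # 400 px at 1 mm^2
  img2 <- planar_image(matrix(c(1, 2, 3, 9), 2))
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2)
  st2 <- roi_stats(img2, mask_roi(m))
  expect_equal(st2$mean, 2)
  expect_equal(st2$sd, 1)
  expect_equal(st2$count, 3)
})

test_that("measured noise SD matches the simulated sigma on a large ROI", {
  ph <- make_uniform_phantom(diameter_mm = 150, signal = 500, noise_sd = 5,
                             seed = 8)
  st <- roi_stats(ph$image, ph$disk)
  expect_gt(st$count, 1e4)
  expect_lt(abs(st$sd - 5) / 5, 0.1)
})

test_that("SNR applies the 0.66 Rayleigh correction to the formula", {
  mk <- function(mean = 0, sd = 1)
    structure(list(mean = mean, sd = sd, max = mean, min = mean,
                   count = 100, roi_area_cm2 = 1), class = "roi_stats")
  expect_equal(snr(mk(100), mk(sd = 0.66)), 100)
  expect_equal(snr(mk(0), mk(sd = 2)), 0)
  expect_error(snr(mk(10), mk(sd = 0)), "positive")
  # linear in signal mean, inversely proportional to noise SD
  expect_equal(snr(mk(200), mk(sd = 5)), 2 * snr(mk(100), mk(sd = 5)))
  expect_equal(snr(mk(100), mk(sd = 10)), snr(mk(100), mk(sd = 5)) / 2)
  # direct formula on simulated stats: mean 200, noise SD 5 -> 26.4
  expect_equal(snr(mk(200), mk(sd = 5)), 26.4)
})

test_that("SNR on a simulated phantom with background noise ROI", {
  ph <- make_uniform_phantom(diameter_mm = 120, signal = 200, noise_sd = 5,
                             n_px = 220, seed = 12)
  sig <- roi_stats(ph$image, ph$disk)
  bg <- matrix(FALSE, 220, 220)
  bg[1:25, 1:25] <- TRUE  # air corner: Rayleigh-like magnitude noise
  noi <- roi_stats(ph$image, mask_roi(bg))
  got <- snr(sig, noi)
  # Rayleigh SD ~ 0.655 sigma, so SNR ~ 200 * 0.66 / (0.655 * 5)
  expect_lt(abs(got - 200 * 0.66 / (0.655 * 5)) / got, 0.15)
})

test_that("percent uniformity and PIU agree and match printed table cells", {
  mk <- function(mn, mx) structure(list(mean = (mn + mx) / 2, sd = 0,
                                        max = mx, min = mn, count = 10,
                                        roi_area_cm2 = 1),
                                   class = "roi_stats")
  expect_equal(percent_uniformity(mk(5, 5)), 100)
  expect_equal(percent_uniformity(mk(0, 7)), 0)
  st <- mk(702.75, 759.16)
  expect_equal(percent_uniformity(st), piu(st$min, st$max, digits = NA))
  expect_equal(round(percent_uniformity(st), 2), 96.14)
  expect_equal(piu(702.75, 759.16), 96.1)
  expect_equal(piu(741.27, 757.2), 98.9)
  expect_equal(piu(2193.23, 2517.25), 93.1)
  expect_equal(piu(5, 5), 100)
  expect_error(piu(10, 5), "exceeds")
  expect_error(percent_uniformity(mk(-10, 5)), "positive")
})

test_that("ghosting ratio matches the printed table cells and symmetry", {
  expect_equal(ghosting_ratio(20.6, 21.2, 33.5, 40.9, 733.2), 0.022)
  expect_equal(ghosting_ratio(24.7, 23.3, 36.9, 35, 749.6), 0.016)
  expect_equal(ghosting_ratio(26.4, 26.1, 24, 21, 2295.3), 0.002)
  expect_equal(ghosting_ratio(12, 18, 10, 20, 500), 0)  # t+b == l+r
  expect_error(ghosting_ratio(1, 1, 1, 1, 0), "positive")
})

test_that("low-contrast counts follow the template ground truth", {
  lc_all <- make_low_contrast_slice(rep(60, 10), noise_sd = 3, seed = 5)
  expect_equal(low_contrast_count(lc_all$image, lc_all$template), 10L)
  lc7 <- make_low_contrast_slice(c(rep(60, 7), 0, 0, 0), noise_sd = 3,
                                 seed = 6)
  expect_equal(low_contrast_count(lc7$image, lc7$template), 7L)
  blank <- make_low_contrast_slice(rep(0, 10), noise_sd = 3, seed = 7)
  expect_equal(low_contrast_count(blank$image, blank$template), 0L)
})

test_that("low-contrast count is monotone nondecreasing in CNR", {
  counts <- vapply(c(0.5, 1.5, 3, 6, 12), function(scale) {
    lc <- make_low_contrast_slice(scale * (10:1), noise_sd = 3, seed = 11)
    low_contrast_count(lc$image, lc$template)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("full LCOD score sums four per-slice counts", {
  expect_equal(full_lcod_score(c(1, 8, 9, 10)), 28L)
  expect_equal(full_lcod_score(c(3, 8, 9, 10)), 30L)
  expect_equal(full_lcod_score(c(8, 9, 10, 10)), 37L)
  expect_equal(full_lcod_score(c(0, 0, 0, 0)), 0L)
  expect_error(full_lcod_score(c(1, 2, 3)), "4 per-slice")
  expect_error(full_lcod_score(c(11, 0, 0, 0)), "0..10")
})

test_that("geometric lengths measure FWHM extents to sub-pixel accuracy", {
  disk <- make_disk_image(n = 240, radius_px = 95, value = 1000, bg = 0,
                          spacing = 1)
  len <- geometric_lengths(disk)
  expect_lt(abs(len[["row"]] - 190), 0.5)
  expect_lt(abs(len[["col"]] - 190), 0.5)
  # spacing scales the physical result
  disk05 <- planar_image(disk$pixels, c(0.5, 0.5))
  len05 <- geometric_lengths(disk05)
  expect_lt(abs(len05[["row"]] - 95), 0.25)
  # ellipse 190 x 148 px
  n <- 240
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  ell <- matrix(0, n, n)
  ell[((rr - 120.5) / 95)^2 + ((cc - 120.5) / 74)^2 <= 1] <- 800
  lene <- geometric_lengths(planar_image(ell, c(1, 1)))
  expect_lt(abs(lene[["row"]] - 190), 0.5)
  expect_lt(abs(lene[["col"]] - 148), 0.5)
  expect_error(geometric_lengths(planar_image(matrix(1, 20, 20))), "flat")
})

test_that("geometric lengths work along volume axes", {
  hv <- make_head_volume(phantom_spec3d(noise_sd = 0))
  len <- geometric_lengths(hv$volume, axes = c("x", "y"))
  # outer skull ellipsoid: 2 x (65, 80) mm
  expect_lt(abs(len[["x"]] - 130), 2 * hv$volume$spacing_mm[1])
  expect_lt(abs(len[["y"]] - 160), 2 * hv$volume$spacing_mm[2])
})

test_that("ACR report bundles the table rows with printed rounding", {
  rep <- acr_report(lcod_counts = c(1, 8, 9, 10),
                    uniformity_low = 702.75, uniformity_high = 759.16,
                    ghost = list(top = 20.6, bottom = 21.2, left = 33.5,
                                 right = 40.9, large_roi = 733.2))
  expect_equal(rep$lcod_full_score, 28L)
  expect_equal(rep$piu_pct, 96.1)
  expect_equal(rep$ghosting_ratio, 0.022)
})
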