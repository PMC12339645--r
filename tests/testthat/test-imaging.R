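plug_layout <- function(mean_hu = 37.3, sd_hu = 5.9) {
  phantom_layout(
    shape = c(220, 220), spacing = 0.01,
    plugs = data.frame(x_cm = 1.1, y_cm = 1.1, radius_cm = 1.0,
                       material = "plug", mean_hu = mean_hu, sd_hu = sd_hu))
}

test_that("layout validation: plugs inside the image and non-overlapping", {
  expect_error(phantom_layout(c(50, 50), 0.01,
                              data.frame(x_cm = 0.1, y_cm = 0.1, radius_cm = 0.3,
                                         material = "p", mean_hu = 0, sd_hu = 0)),
               class = "ctcal_validation_error")
  expect_error(phantom_layout(c(200, 200), 0.01,
                              data.frame(x_cm = c(0.8, 1.0), y_cm = c(1, 1),
                                         radius_cm = c(0.3, 0.3),
                                         material = c("a", "b"),
                                         mean_hu = c(0, 0), sd_hu = c(0, 0))),
               class = "ctcal_validation_error")
})

test_that("noiseless generation is exactly piecewise constant; seeded generation reproducible", {
  lay <- plug_layout(mean_hu = 23.3, sd_hu = 0)
  img <- generate_phantom_image(lay, seed = 5)
  mask <- circular_roi_mask(lay$shape, c(1.1, 1.1), lay$spacing, diameter = 1.0)
  expect_true(all(img[mask] == 23.3))
  expect_true(all(img[!mask] %in% c(0, 23.3)))

  noisy <- plug_layout()
  a <- generate_phantom_image(noisy, seed = 99)
  b <- generate_phantom_image(noisy, seed = 99)
  expect_identical(a, b)
  c2 <- generate_phantom_image(noisy, seed = 100)
  expect_false(identical(a, c2))
})

test_that("circular ROI mask follows pixel-center containment and the area law", {
  m <- circular_roi_mask(c(200, 200), center = c(1, 1), spacing = 0.01,
                         diameter = 1.53)
  expect_equal(sum(m), pi * 0.765^2 / 0.01^2, tolerance = 0.02)

  coarse <- circular_roi_mask(c(10, 10), center = c(0.5, 0.5), spacing = 0.1,
                              diameter = 0.2)
  expect_gte(sum(coarse), 1)

  expect_error(circular_roi_mask(c(100, 100), center = c(0, 0), spacing = 0.01),
               class = "ctcal_validation_error")
})

test_that("ROI statistics recover generating parameters within CLT / chi-square bounds", {
  lay <- plug_layout(mean_hu = 37.3, sd_hu = 5.9)
  img <- generate_phantom_image(lay, seed = 2024)
  mask <- circular_roi_mask(lay$shape, c(1.1, 1.1), lay$spacing)
  st <- roi_statistics(img, mask)
  expect_gt(st$n, 1e4)
  expect_lt(abs(st$mean_hu - 37.3), 3 * 5.9 / sqrt(st$n))
  expect_lt(abs(st$sd_hu - 5.9) / 5.9, 0.05)
  expect_equal(sum(st$histogram$count), st$n)
})

test_that("ROI statistics: constant image, tiny arithmetic case, histogram consistency", {
  img <- matrix(7, 10, 10)
  st <- roi_statistics(img, matrix(TRUE, 10, 10))
  expect_equal(st$sd_hu, 0)
  expect_equal(sum(st$histogram$count > 0), 1)

  img2 <- matrix(c(10, 20, 30, 99), 2)
  mask2 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2)
  st2 <- roi_statistics(img2, mask2)
  expect_equal(st2$mean_hu, 20)
  expect_equal(st2$sd_hu, sqrt(mean((c(10, 20, 30) - 20)^2)))

  # mean recomputed from fine-binned histogram agrees with the direct mean
  lay <- plug_layout()
  img3 <- generate_phantom_image(lay, seed = 3)
  mask3 <- circular_roi_mask(lay$shape, c(1.1, 1.1), lay$spacing)
  st3 <- roi_statistics(img3, mask3, bin_width = 0.5)
  centers <- (st3$histogram$bin_left + st3$histogram$bin_right) / 2
  hist_mean <- sum(centers * st3$histogram$count) / st3$n
  expect_lt(abs(hist_mean - st3$mean_hu), 0.25)

  expect_error(roi_statistics(img, matrix(FALSE, 10, 10)),
               class = "ctcal_validation_error")
})

test_that("cohort aggregation uses the mean-of-means / mean-of-SDs convention", {
  single <- summarize_cohort(data.frame(mean_hu = 5, sd_hu = 2))
  expect_equal(single$mean_hu, 5)
  expect_equal(single$sd_hu, 2)

  cases <- data.frame(mean_hu = c(30, 40, 35), sd_hu = c(10, 14, 12))
  out <- summarize_cohort(cases)
  expect_equal(out$mean_hu, 35)
  expect_equal(out$sd_hu, 12)
  # permutation invariance
  shuffled <- summarize_cohort(cases[c(3, 1, 2), ])
  expect_equal(out$mean_hu, shuffled$mean_hu)
  expect_equal(out$sd_hu, shuffled$sd_hu)

  expect_error(summarize_cohort(data.frame(mean_hu = numeric(),
                                           sd_hu = numeric())),
               class = "ctcal_validation_error")
})

test_that("dose grid generation: patterns, determinism, unknown pattern rejected", {
  u <- generate_dose_grid(c(12, 12, 12), "uniform", list(dose = 30))
  expect_true(all(u$dose[u$mask] == 30))
  expect_true(all(u$dose[!u$mask] == 0))

  r <- generate_dose_grid(c(20, 16, 16), "linear_ramp", list(low = 0, high = 100))
  expect_equal(min(r$dose[r$mask]), 0)
  expect_equal(max(r$dose[r$mask]), 100)

  s1 <- generate_dose_grid(c(16, 16, 16), "spherical_falloff",
                           list(noise_sd = 0.5), seed = 8)
  s2 <- generate_dose_grid(c(16, 16, 16), "spherical_falloff",
                           list(noise_sd = 0.5), seed = 8)
  expect_identical(s1$dose, s2$dose)

  expect_error(generate_dose_grid(c(10, 10, 10), "swirl"),
               class = "ctcal_validation_error")
})
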