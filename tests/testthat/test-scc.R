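published_params <- function() scc_parameters(k1 = 1.6e-3, k2 = 2.7e-5, alpha = 0.98)

test_that("electron-fraction power sums: single element, exponent zero, water value", {
  o8 <- data.frame(element = "O", mass_fraction_percent = 100)
  expect_equal(electron_fraction_power_sum(o8, 1.86), 8^1.86)
  expect_equal(electron_fraction_power_sum(bdp_material(), 0), 1)
  s_w <- electron_fraction_power_sum(water_material(), 1.86)
  expect_equal(s_w, oracle_power_sum(oracle_water, 1.86), tolerance = 1e-10)
  expect_equal(s_w, 38.47, tolerance = 1e-3)
})

test_that("relative attenuation reduces to electron density and is 1 for water", {
  params <- published_params()
  expect_equal(relative_attenuation(water_material(), params), 1)
  zero_k <- scc_parameters(0, 0, 1)
  for (mat in list(bdp_material(), icrp110_brain_material())) {
    expect_equal(relative_attenuation(mat, zero_k),
                 relative_electron_density(mat), tolerance = 1e-12)
  }
  # 1.047 to the 4 printed significant figures
  u_brain <- relative_attenuation(icrp110_brain_material(), params)
  expect_equal(u_brain, 1.047, tolerance = 5e-4)
  expect_equal(u_brain,
               oracle_hu(oracle_comp(icrp110_brain_material()), 1.05,
                         1.6e-3, 2.7e-5, 1) / 1000 + 1,
               tolerance = 1e-10)
})

test_that("predicted CT number: water pins 0 HU for any parameters; density monotonicity", {
  set.seed(7)
  for (rep in 1:20) {
    p <- scc_parameters(runif(1, 0, 5e-3), runif(1, 0, 1e-4), runif(1, 0.8, 1.2))
    expect_identical(predicted_ct_number(water_material(), p), 0)
  }
  p <- published_params()
  comp <- as.data.frame(water_material())[c("element", "mass_fraction_percent")]
  hu <- sapply(c(0.9, 1.0, 1.1, 1.5),
               function(rho) predicted_ct_number(ct_material(comp, "w", rho), p))
  expect_true(all(diff(hu) > 0))
  # pure density scaling with k1 = k2 = 0, alpha = 1: 1000*(rho_e - 1)
  expect_equal(predicted_ct_number(ct_material(comp, "w", 1.10),
                                   scc_parameters(0, 0, 1)),
               100, tolerance = 1e-9)
})

test_that("predicted CT numbers agree with the independent brute-force oracle on all fixtures", {
  p <- published_params()
  for (mat in list(bdp_material(), icrp110_brain_material(), air_material())) {
    expect_equal(predicted_ct_number(mat, p),
                 oracle_hu(oracle_comp(mat), mass_density(mat),
                           p$k1, p$k2, p$alpha),
                 tolerance = 1e-10)
  }
})

test_that("noiseless generate-then-fit round trip recovers the parameters", {
  mats <- fit_material_set()
  truth <- published_params()
  hu <- vapply(mats, predicted_ct_number, numeric(1), params = truth)
  pts <- calibration_points(mats, hu)
  fit <- fit_scc(pts)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-6)
  expect_equal(fit$parameters$k1, truth$k1, tolerance = 1e-3)
  expect_equal(fit$parameters$k2, truth$k2, tolerance = 1e-3)
  expect_equal(fit$parameters$alpha, truth$alpha, tolerance = 1e-3)
  expect_equal(fit$objective, sum(fit$residuals$residual_hu^2), tolerance = 1e-9)

  td <- tidy(fit)
  expect_equal(td$term, c("k1", "k2", "alpha"))
  expect_equal(glance(fit)$n_points, length(mats))
})

test_that("a perfect start leaves parameters essentially unchanged with zero objective", {
  mats <- fit_material_set()
  truth <- published_params()
  hu <- vapply(mats, predicted_ct_number, numeric(1), params = truth)
  fit <- fit_scc(calibration_points(mats, hu), initial = truth)
  expect_lt(fit$objective, 1e-10)
  expect_equal(fit$parameters$k1, truth$k1, tolerance = 1e-4)
  expect_equal(fit$parameters$alpha, truth$alpha, tolerance = 1e-6)
})

test_that("underdetermined and degenerate calibrations are rejected or flagged", {
  mats <- fit_material_set()
  truth <- published_params()
  hu <- vapply(mats, predicted_ct_number, numeric(1), params = truth)
  expect_error(fit_scc(calibration_points(mats[1:2], hu[1:2])),
               class = "ctcal_validation_error")
  # the air/lung/bone three-point set is accepted but flagged as weak
  trio <- list(air_material(), lung_like_material(), bone_like_material())
  hu3 <- vapply(trio, predicted_ct_number, numeric(1), params = truth)
  expect_warning(fit_scc(calibration_points(trio, hu3)),
                 class = "ctcal_weak_calibration")
  expect_error(calibration_points(mats[c(1, 1, 2)], c(0, 0, 0)),
               class = "ctcal_validation_error")
})

test_that("parameter recovery holds across randomly drawn ground truths", {
  mats <- fit_material_set()
  set.seed(20240917)
  for (rep in 1:20) {
    truth <- scc_parameters(runif(1, 5e-4, 5e-3), runif(1, 1e-5, 1e-4),
                            runif(1, 0.9, 1.1))
    hu <- vapply(mats, predicted_ct_number, numeric(1), params = truth)
    fit <- fit_scc(calibration_points(mats, hu))
    expect_equal(fit$parameters$k1, truth$k1, tolerance = 1e-3)
    expect_equal(fit$parameters$k2, truth$k2, tolerance = 1e-3)
    expect_equal(fit$parameters$alpha, truth$alpha, tolerance = 1e-3)
  }
})

test_that("1 HU measurement noise perturbs refitted predictions by the same order", {
  mats <- fit_material_set()
  truth <- published_params()
  hu <- vapply(mats, predicted_ct_number, numeric(1), params = truth)
  set.seed(11)
  for (rep in 1:5) {
    noisy <- hu + rnorm(length(hu), 0, 1)
    fit <- fit_scc(calibration_points(mats, noisy))
    pred <- vapply(mats, predicted_ct_number, numeric(1),
                   params = fit$parameters)
    expect_lt(max(abs(pred - hu)), 10)  # O(sigma), no blow-up
  }
})
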