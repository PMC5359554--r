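test_that("the objective is zero at a perfect fit and sums log10 residuals", {
  sc <- quick_calib_config()
  p <- tlk_params()
  doses <- c(0.5, 1, 2, 4)
  sim <- simulate_sf(sc, p, doses)
  data <- survival_curve_data(doses, sim$sf)
  expect_equal(objective(p, data, sc), 0)
  # one point off by a factor of 10 contributes exactly 1
  off <- data
  off$sf[2] <- off$sf[2] / 10
  expect_equal(objective(p, off, sc), 1, tolerance = 1e-10)
  # term-by-term oracle on a perturbed curve
  noisy <- survival_curve_data(doses, pmin(1, sim$sf * c(1.1, 0.8, 1.3, 0.7)))
  manual <- sum((log10(sim$sf) - log10(noisy$sf))^2)
  expect_equal(objective(p, noisy, sc), manual, tolerance = 1e-12)
  # order of data points is irrelevant
  shuffled <- noisy[c(3, 1, 4, 2), ]
  expect_equal(objective(p, shuffled, sc), objective(p, noisy, sc),
               tolerance = 1e-12)
  # linear-scale option
  expect_equal(objective(p, noisy, sc, scale = "linear"),
               sum((sim$sf - noisy$sf)^2), tolerance = 1e-12)
})

test_that("sensitivity scans detect null and dominant parameters", {
  sc <- quick_calib_config()
  truth <- tlk_params()
  data <- make_survival_curve(sc, truth)
  # lethal_pair_frac is inert when eta = 0
  p0 <- tlk_params(eta_per_h = 0)
  scan0 <- sensitivity_scan(data, sc, p0, "lethal_pair_frac")
  expect_equal(attr(scan0, "obj_range"), 0, tolerance = 1e-12)
  # at the generator parameters, eta's range exceeds beta1's
  scan_eta <- sensitivity_scan(data, sc, truth, "eta_per_h")
  scan_b1 <- sensitivity_scan(data, sc, truth, "beta1")
  expect_gt(attr(scan_eta, "obj_range"), attr(scan_b1, "obj_range"))
  # the scan of each parameter at its generating value attains its minimum
  # at the unit factor
  expect_equal(scan_eta$factor[which.min(scan_eta$obj)], 1)
  expect_error(sensitivity_scan(data, sc, truth, "nope"), "unknown")
  expect_error(sensitivity_scan(data, sc, truth, "beta1", factors = 1),
               "2 points")
})

test_that("calibration recovers generator parameters from noise-free data", {
  sc <- quick_calib_config()
  truth <- tlk_params()
  curve <- make_survival_curve(sc, truth)
  fit <- calibrate(curve, sc)
  expect_lt(abs(log10(fit$params$beta1 / truth$beta1)), log10(1.1))
  expect_lt(abs(log10(fit$params$beta2 / truth$beta2)), log10(1.1))
  expect_lt(abs(log10(fit$params$eta_per_h / truth$eta_per_h)), log10(1.1))
  expect_lt(fit$obj_value, 1e-10)
  expect_lte(fit$obj_value, fit$initial_obj)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(td$term, c("beta1", "beta2", "eta_per_h"))
  expect_equal(glance(fit)$obj_value, fit$obj_value)
})

test_that("calibration returns the start when the data equal its output", {
  sc <- quick_calib_config()
  truth <- tlk_params()
  curve <- make_survival_curve(sc, truth)
  fit <- calibrate(curve, sc, start = truth)
  expect_equal(fit$initial_obj, 0)
  expect_identical(fit$params$beta1, truth$beta1)
  expect_identical(fit$params$eta_per_h, truth$eta_per_h)
  expect_equal(fit$obj_value, 0)
})

test_that("noisy curves are fitted to the noise floor with eta identified", {
  sc <- quick_calib_config()
  truth <- tlk_params()
  noise <- 0.03
  curve <- make_survival_curve(sc, truth, noise = noise, seed = 7)
  fit <- calibrate(curve, sc)
  # expected OBJ if the truth curve were refit: ~ n * (noise/ln10)^2
  floor_est <- nrow(curve) * (noise / log(10))^2
  expect_lt(fit$obj_value, 3 * floor_est)
  # eta is the identifiable parameter; the nearly collinear lethality
  # fractions are not resolvable at this noise level
  expect_lt(abs(log10(fit$params$eta_per_h / truth$eta_per_h)), log10(2))
  expect_lte(fit$obj_value, fit$initial_obj)
})

test_that("recovery succeeds from random log-uniform starts", {
  sc <- quick_calib_config()
  truth <- tlk_params()
  curve <- make_survival_curve(sc, truth)
  ok <- 0
  for (s in 1:10) {
    fit <- calibrate(curve, sc, start = "random", seed = s)
    hit <- abs(log10(fit$params$beta1 / truth$beta1)) < log10(1.1) &&
      abs(log10(fit$params$beta2 / truth$beta2)) < log10(1.1) &&
      abs(log10(fit$params$eta_per_h / truth$eta_per_h)) < log10(1.1)
    ok <- ok + hit
    expect_lte(fit$obj_value, fit$initial_obj)
  }
  expect_gte(ok, 8)
})

test_that("survival-curve IO and calibration reports round-trip", {
  data <- survival_curve_data(c(0.1, 1, 2), c(0.98, 0.8, 0.6))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data, path)
  back <- read_survival_curve(path)
  expect_equal(back$sf, data$sf)
  expect_error(survival_curve_data(c(1, 2), c(0.5, 1.2)), "0, 1")
  sc <- quick_calib_config(n_nuclei = 8)
  curve <- make_survival_curve(sc, tlk_params())
  fit <- calibrate(curve, sc)
  rep_path <- withr::local_tempfile(fileext = ".json")
  write_calibration_report(fit, rep_path)
  rep <- jsonlite::read_json(rep_path)
  expect_equal(rep$params$beta2, fit$params$beta2, tolerance = 1e-12)
})
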