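test_that("sensor response matches Hill arithmetic and its limits", {
  glu <- hill_sensor("glucose", y_min = 1 / 18, y_max = 1, ec50 = 0.1)
  # zero-dose limit and half-max identity hold for any slope
  for (n in c(0.5, 1, 2, 4)) {
    s <- hill_sensor("s", y_min = 0.2, y_max = 3, ec50 = 0.7, hill_n = n)
    expect_equal(sensor_response(s, 0), 0.2)
    expect_equal(sensor_response(s, 0.7), (0.2 + 3) / 2)
    d <- hill_sensor("d", y_min = 0.2, y_max = 3, ec50 = 0.7, hill_n = n,
                     mode = "depletion_activating")
    expect_equal(sensor_response(d, 0), 3)
    expect_equal(sensor_response(d, 0.7), (0.2 + 3) / 2)
  }
  # direct arithmetic: 1/18 + (17/18) * 0.4/(0.1+0.4)
  expect_equal(sensor_response(glu, 0.4), 1 / 18 + (17 / 18) * 0.8,
               tolerance = 1e-12)
  expect_error(sensor_response(glu, -0.1), "stimulus")
})

test_that("sensor response is monotone and bounded", {
  s_up <- hill_sensor("a", y_min = 0.05, y_max = 1, ec50 = 5, hill_n = 1.7)
  s_dn <- hill_sensor("d", y_min = 0.05, y_max = 1, ec50 = 5, hill_n = 1.7,
                      mode = "depletion_activating")
  x <- seq(0, 50, length.out = 400)
  expect_true(all(diff(sensor_response(s_up, x)) > 0))
  expect_true(all(diff(sensor_response(s_dn, x)) < 0))
  for (s in list(s_up, s_dn)) {
    y <- sensor_response(s, x)
    expect_true(all(y >= s$y_min - 1e-12 & y <= s$y_max + 1e-12))
  }
})

test_that("RPU conversion is linear with the published calibration", {
  cal <- sensor_calibration()
  expect_equal(rpu_from_fluorescence(500, 500, cal), 0)
  expect_equal(rpu_from_fluorescence(737, 500, cal), 0.237)
  expect_equal(rpu_from_fluorescence(1846, 500, cal), 1.346)
  # linearity in (fluor - background)
  d <- runif(20, 0, 5000)
  expect_equal(rpu_from_fluorescence(1000 + d, 1000, cal), d * 1e-3)
  expect_error(rpu_from_fluorescence(10, 20, cal), "miscalibrat")
})

test_that("dynamic range is y_max over y_min", {
  expect_equal(dynamic_range(hill_sensor("g", 0.05, 0.05 * 18, 1)), 18)
  expect_equal(dynamic_range(hill_sensor("a", 0.004, 0.004 * 250, 1)), 250)
  expect_equal(dynamic_range(hill_sensor("c", 0.3, 0.3 + 1e-9, 1)), 1,
               tolerance = 1e-6)
})

test_that("sensor invariants are enforced at construction", {
  expect_error(hill_sensor("x", 1, 1, 1), "y_max > y_min")
  expect_error(hill_sensor("x", 0.1, 1, -1), "ec50")
  expect_error(hill_sensor("x", 0.1, 1, 1, hill_n = 0), "hill_n")
})

test_that("sensor YAML round-trips losslessly", {
  s <- hill_sensor("oxygen", y_min = 0.04, y_max = 1, ec50 = 36,
                   hill_n = 1.3, mode = "depletion_activating",
                   stimulus_units = "umol/l DO")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sensor_yaml(s, path)
  s2 <- read_sensor_yaml(path)
  expect_equal(unclass(s2), unclass(s))
})

test_that("hill fitting recovers generating parameters exactly on noiseless data", {
  gen <- hill_sensor("acetate", y_min = 1 / 250, y_max = 1, ec50 = 13.8,
                     hill_n = 1)
  doses <- c(0, exp(seq(log(0.5), log(100), length.out = 11)))
  dr <- generate_dose_response(gen, doses, noise_cv = 0, n_rep = 1)
  f <- fit_hill(dr, mode = "activating")
  expect_false(f$poor_fit)
  expect_equal(f$estimates[["ec50"]], 13.8, tolerance = 1e-6)
  expect_equal(f$estimates[["y_max"]], 1, tolerance = 1e-6)
  expect_equal(f$estimates[["hill_n"]], 1, tolerance = 1e-5)
  # depletion mode too
  gen_d <- hill_sensor("oxygen", y_min = 0.04, y_max = 1, ec50 = 36,
                       hill_n = 1, mode = "depletion_activating")
  dr_d <- generate_dose_response(gen_d, reference_dose_grid("oxygen"),
                                 noise_cv = 0, n_rep = 1)
  f_d <- fit_hill(dr_d, mode = "depletion_activating")
  expect_equal(f_d$estimates[["ec50"]], 36, tolerance = 1e-6)
})

test_that("hill fitting recovers ec50 within 10% under measurement noise", {
  # the tolerance describes the estimator's median behavior over noise
  # draws (single draws at 3 replicates x 5% CV have ~6% ec50 sd)
  gen <- default_sensors()$glucose
  doses <- reference_dose_grid("glucose")
  errs <- vapply(1:20, function(sd) {
    f <- fit_hill(generate_dose_response(gen, doses, 0.05, 3, seed = sd),
                  mode = "activating")
    abs(f$estimates[["ec50"]] / 0.1 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("model-mismatched data are flagged as a poor fit", {
  dr <- dose_response(c(1, 2, 4, 8, 16),
                      matrix(c(10, 8, 5, 2, 1), ncol = 1))
  f <- fit_hill(dr, mode = "activating")
  expect_true(f$poor_fit)
})

test_that("dose-response container validates and round-trips CSV", {
  expect_error(dose_response(c(1, 1, 2), matrix(1, 3, 1)), "ascending")
  expect_error(dose_response(c(-1, 2), matrix(1, 2, 1)), "non-negative")
  dr <- dose_response(c(0, 1, 2, 4), matrix(runif(12), ncol = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_response_csv(dr, path)
  dr2 <- read_dose_response_csv(path)
  expect_equal(dr2$doses, dr$doses)
  expect_equal(unname(dr2$responses), unname(dr$responses))
})
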