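test_that("no-op calibration evaluates constraints without searching", {
  res <- calibrate(pdu_model_parameters(), calibration_targets(),
                   default_growth(), free = character(0))
  expect_length(res$fitted, 0)
  expect_named(res$constraints_satisfied,
               c("depletion_in_window", "prop_onset", "poh_onset",
                 "pald_peak"))
  # shipped defaults are themselves a feasible point of the criteria
  expect_true(all(res$constraints_satisfied))
  expect_equal(res$stats$pald_peak_mM, 14.1, tolerance = 0.05)
})

test_that("full calibration finds a feasible point for the stated criteria", {
  cal <- cached_calibration()
  expect_true(all(cal$constraints_satisfied))
  expect_lte(cal$stats$pald_peak_mM, 16)
  expect_gte(cal$stats$pdo_depletion_h, 10)
  expect_lte(cal$stats$pdo_depletion_h, 20)
  expect_lt(abs(cal$stats$prop_onset_h - 10), 1)
  expect_lt(abs(cal$stats$poh_onset_h - 10), 1)
  expect_named(cal$fitted, c("k_c", "vmax_P", "vmax_Q"))
})

test_that("calibration is deterministic given the grid specification", {
  g <- default_growth()
  a <- calibrate(pdu_model_parameters(), calibration_targets(), g,
                 free = "k_c", grid_points = 3, grid_decades = 1,
                 refine_maxit = 10)
  b <- calibrate(pdu_model_parameters(), calibration_targets(), g,
                 free = "k_c", grid_points = 3, grid_decades = 1,
                 refine_maxit = 10)
  expect_identical(a$fitted, b$fitted)
  expect_identical(a$objective_value, b$objective_value)
})

test_that("raising shell permeability weakly accelerates substrate depletion", {
  g <- default_growth()
  deps <- vapply(c(2000, 5000, 20000), function(kc) {
    p <- set_param(pdu_model_parameters(), "k_c", kc)
    s <- run_simulation(p, g, rtol = 1e-6, atol = 1e-8)
    ser <- concentration_series(s, "external", "PDO")
    depletion_time(ser$time_h, ser$concentration_mM)
  }, numeric(1))
  expect_true(all(diff(deps) <= 1e-6))
})

test_that("least-squares fit is exact at truth and recovers a perturbed k_c", {
  g <- default_growth()
  truth <- pdu_model_parameters()
  obs <- generate_dataset(truth, growth_model(),
                          noise_model(cv = 0, detection_floor_mM = 0))
  # objective at truth is (numerically) zero
  fit0 <- fit_to_timeseries(truth, obs$measurements, g, free = "k_c")
  expect_lt(fit0$objective_value, 1e-6)
  expect_equal(unname(fit0$fitted["k_c"]), 5000, tolerance = 0.01)

  start <- set_param(truth, "k_c", 5000 * 5)
  fit <- fit_to_timeseries(start, obs$measurements, g, free = "k_c")
  expect_equal(unname(fit$fitted["k_c"]), 5000, tolerance = 0.05)

  expect_error(fit_to_timeseries(truth,
                                 data.frame(time_h = 1, species = "XXX",
                                            concentration_mM = 1),
                                 g, free = "k_c"), "not in the model")
})
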