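test_that("growth-curve construction validates its inputs", {
  expect_error(growth_curve(0, 1e7), "at least 2")
  expect_error(growth_curve(c(0, 0), c(1e7, 1e7)), "strictly increasing")
  expect_error(growth_curve(c(0, 1), c(1e7, 0)), "positive")
})

test_that("interpolation is exponential between samples, constant outside", {
  g <- growth_curve(c(0, 10), c(1e7, 1e9))
  # log-linear: halfway in time is the geometric mean
  expect_equal(growth_density(g, 5), sqrt(1e7 * 1e9))
  expect_equal(growth_density(g, -5), 1e7)
  expect_equal(growth_density(g, 25), 1e9)
})

test_that("doubling time inverts an exact exponential", {
  tt <- seq(0, 10, 0.5)
  g <- growth_curve(tt, 1e7 * 2^(tt / 2))
  expect_equal(doubling_time(g, c(0, 10)), 2.0, tolerance = 1e-12)

  flat <- growth_curve(c(0, 5, 10), rep(1e8, 3))
  expect_warning(td <- doubling_time(flat, c(0, 10)), "infinite")
  expect_identical(td, Inf)

  expect_error(doubling_time(g, c(20, 30)), "at least 2")
})

test_that("windowed doubling times recover the generator's phases", {
  gm <- growth_model() # td 3.17 h early, 9.2 h late
  gc <- generate_growth_curve(gm)
  expect_equal(growth_density(gc, 0), gm$n0_cells_ml)
  expect_equal(doubling_time(gc, c(3, 9)), 3.17, tolerance = 0.02)
  expect_equal(doubling_time(gc, c(12.5, 18)), 9.2, tolerance = 0.02)
  # lag phase is flat
  expect_equal(growth_density(gc, 0.5), gm$n0_cells_ml)
})
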