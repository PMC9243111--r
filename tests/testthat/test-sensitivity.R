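test_that("central log-log slopes are exact for power-law functionals", {
  p <- pdu_model_parameters()
  g <- default_growth()
  # QoI that reads a parameter directly: Q = c * k_c  =>  S = 1
  lin <- function(sim) 3 * sim$params$k_c_um_h
  cub <- function(sim) 0.5 * sim$params$k_c_um_h^3
  cst <- function(sim) 42
  fast <- list(rtol = 1e-4, atol = 1e-6, t_span = c(0, 1))
  s_lin <- do.call(local_sensitivity,
                   c(list(p, g, "k_c", qoi = lin), fast))
  s_cub <- do.call(local_sensitivity,
                   c(list(p, g, "k_c", qoi = cub), fast))
  s_cst <- do.call(local_sensitivity,
                   c(list(p, g, "k_c", qoi = cst), fast))
  expect_equal(s_lin$S, 1, tolerance = 1e-10)
  # cubic central difference carries an error of exactly rel_step^2
  expect_equal(s_cub$S, 3 + 0.01^2, tolerance = 1e-10)
  expect_equal(s_cst$S, 0)
  # the O(rel_step^2) error shrinks 4x when the step is halved
  s_cub2 <- do.call(local_sensitivity,
                    c(list(p, g, "k_c", qoi = cub, rel_step = 0.005), fast))
  expect_equal(abs(s_cub2$S - 3) * 4, abs(s_cub$S - 3), tolerance = 1e-6)
})

test_that("sweep rejects duplicates and reports every parameter once", {
  p <- pdu_model_parameters()
  g <- default_growth()
  expect_error(sensitivity_sweep(p, g, parameters = c("k_c", "k_c")),
               "duplicate")
  sw <- sensitivity_sweep(p, g, parameters = c("k_c", "vmax_CDE"),
                          rel_step = 0.01, rtol = 1e-6, atol = 1e-8)
  expect_setequal(sw$parameter, c("k_c", "vmax_CDE"))
  expect_true(all(diff(abs(sw$S)) <= 0))
})

test_that("total surface area dominates the morphological features", {
  p <- pdu_model_parameters()
  g <- default_growth()
  sw <- sensitivity_sweep(p, g, parameters = "morphological",
                          rtol = 1e-6, atol = 1e-8)
  expect_equal(sw$parameter[1], "total_surface_area")
  expect_gt(abs(sw$S[1]), max(abs(sw$S[-1])))
  # ranking of the leading feature is robust to halving/doubling the step
  for (e in c(0.005, 0.02)) {
    swe <- sensitivity_sweep(p, g, parameters = "morphological",
                             rel_step = e, rtol = 1e-6, atol = 1e-8)
    expect_equal(swe$parameter[1], "total_surface_area")
  }
})
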