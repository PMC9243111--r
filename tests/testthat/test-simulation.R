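test_that("an isolated system stays at its initial condition", {
  p <- transport_only_params(k_c = 0, k_m = 0)
  s <- run_simulation(p, flat_growth(), t_span = c(0, 10))
  expect_equal(unname(s$state[, "external.PDO"]),
               rep(55, length(s$times)), tolerance = 1e-10)
  expect_true(all(abs(s$state[, colnames(s$state) != "external.PDO"]) < 1e-10))
})

test_that("transport-only relaxation reaches the volume-weighted equilibrium", {
  p <- transport_only_params()
  g <- flat_growth(5e8)
  s <- run_simulation(p, g, t_span = c(0, 200), output_dt = 1)
  rho <- 5e8 / 1e12
  Vl <- p$compartments$total_volume_um3
  Vcyt <- cytosol_volume(p)
  ceq <- 55 / (1 + rho * (Vl + Vcyt)) # equal concentration in all regions
  final <- s$state[nrow(s$state), ]
  expect_equal(unname(final["external.PDO"]), ceq, tolerance = 1e-6)
  expect_equal(unname(final["cytosol.PDO"]), ceq, tolerance = 1e-6)
  expect_equal(unname(final["lumen.PDO"]), ceq, tolerance = 1e-6)
  expect_lt(s$diagnostics$conservation_residual, 1e-6)
})

test_that("threshold-crossing summaries interpolate linearly", {
  tt <- 0:10
  expect_true(is.na(onset_time(tt, rep(0, 11), 2)))
  expect_equal(onset_time(tt, tt, 2), 2.0)         # ramp c(t) = t
  expect_true(is.na(depletion_time(tt, rep(5, 11), 1)))
  t2 <- seq(0, 12, 0.5)
  expect_equal(depletion_time(t2, 55 - 5 * t2, 0.55), 10.89)
  expect_error(onset_time(numeric(0), numeric(0), 1), "nonempty")
  expect_error(onset_time(tt, tt, -1), "positive")
})

test_that("peak refinement is exact for a sampled parabola", {
  tt <- 0:10
  v <- -(tt - 5)^2 + 9
  expect_equal(peak(tt, v), c(t_peak = 5, c_peak = 9))
  # off-grid vertex
  v2 <- -(tt - 4.3)^2 + 2
  expect_equal(unname(peak(tt, v2)["t_peak"]), 4.3, tolerance = 1e-12)
  # monotone decreasing: boundary maximum, unrefined
  expect_equal(peak(tt, 10 - tt), c(t_peak = 0, c_peak = 10))
})

test_that("summaries are stable under grid refinement and replay", {
  p <- pdu_model_parameters()
  g <- default_growth()
  a <- cached_base_sim()
  b <- run_simulation(p, g, output_dt = 0.05)
  for (sp in c("PDO", "PALD", "PROP")) {
    sa <- concentration_series(a, "external", sp)
    sb <- concentration_series(b, "external", sp)
    if (sp == "PDO") {
      expect_lt(abs(depletion_time(sa$time_h, sa$concentration_mM) -
                      depletion_time(sb$time_h, sb$concentration_mM)), 0.1)
    } else {
      expect_lt(abs(onset_time(sa$time_h, sa$concentration_mM, 1) -
                      onset_time(sb$time_h, sb$concentration_mM, 1)), 0.1)
      expect_lt(abs(peak(sa$time_h, sa$concentration_mM)["t_peak"] -
                      peak(sb$time_h, sb$concentration_mM)["t_peak"]), 0.1)
    }
  }
  # deterministic replay: identical inputs give bit-identical output
  a2 <- run_simulation(p, g)
  expect_identical(a$state, a2$state)
})

test_that("trajectory export is tidy and complete", {
  s <- cached_base_sim()
  d <- as.data.frame(s)
  expect_named(d, c("time_h", "region", "species", "concentration_mM"))
  expect_equal(nrow(d), length(s$times) * 15)
  expect_setequal(unique(d$region), c("lumen", "cytosol", "external"))
  ser <- concentration_series(s, "external", "PDO")
  expect_equal(ser$concentration_mM,
               d$concentration_mM[d$region == "external" & d$species == "PDO"])
  expect_error(concentration_series(run_simulation(pdu_model_parameters(),
                                                   default_growth(),
                                                   t_span = c(0, 1),
                                                   model = "wellmixed"),
                                    "lumen", "PDO"), "not present")
})

test_that("geometry comparison reproduces the microtube limiting cases", {
  g <- default_growth()
  p <- pdu_model_parameters()
  cmp <- compare_geometries(p, growth = g)
  expect_setequal(cmp$summary$scenario, c("base", "equal_volume", "equal_area"))
  s <- cmp$summary
  base <- s[s$scenario == "base", ]
  ev <- s[s$scenario == "equal_volume", ]
  ea <- s[s$scenario == "equal_area", ]
  # equal-volume microtubes expose ~1.9x area and raise the aldehyde peak
  expect_equal(ev$total_area_um2 / base$total_area_um2,
               sa_v_fold_factor(70, 25), tolerance = 1e-10)
  expect_gt(ev$peak_external_pald_mM, base$peak_external_pald_mM)
  # equal-area microtubes concentrate enzymes 1.9x and change little
  expect_equal(ea$lumen_vmax_scale, sa_v_fold_factor(70, 25),
               tolerance = 1e-10)
  dev <- external_rel_dev(cmp$sims$equal_area, cmp$sims$base)
  expect_lt(max(dev), 0.10)

  only_base <- compare_geometries(p, modes = character(0), growth = g)
  expect_equal(only_base$summary$scenario, "base")
})
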