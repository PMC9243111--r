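test_that("Michaelis-Menten rate law identities", {
  expect_equal(mm_rate(5, 10, 5), 5)            # half saturation
  expect_equal(mm_rate(0, 10, 5), 0)
  expect_equal(mm_rate(20, 10, 5), 8.0)
  expect_warning(r <- mm_rate(-1, 10, 5), "clamped")
  expect_equal(r, 0)
  expect_error(mm_rate(1, 10, 0), "km")

  # monotone and bounded by vmax
  s <- sort(runif(50, 0, 1000))
  r <- mm_rate(s, 7, 3)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= 7))
})

test_that("reversible rate reduces to the irreversible law and nets fluxes", {
  kin <- enzyme_kinetics("PduP", vmax_fwd = 10, km_fwd = 5,
                         vmax_rev = 4, km_rev = 2)
  expect_equal(net_reversible_rate(5, 2, kin), 5 - 2)
  expect_equal(net_reversible_rate(0, 0, kin), 0)
  irr <- enzyme_kinetics("PduP", vmax_fwd = 10, km_fwd = 5)
  for (s in c(0, 1, 10, 100)) {
    expect_equal(net_reversible_rate(s, 99, irr), mm_rate(s, 10, 5))
  }
})

test_that("transport flux is linear in the gradient and antisymmetric", {
  expect_equal(transport_flux(1, 2, 3, 1), 4)
  expect_equal(transport_flux(5, 7, 2.5, 2.5), 0)
  expect_equal(transport_flux(0, 7, 100, 0), 0)
  for (i in 1:10) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100)
    expect_equal(transport_flux(3, 2, a, b), -transport_flux(3, 2, b, a))
  }
})

test_that("the zero state is a fixed point of both right-hand sides", {
  p <- pdu_model_parameters()
  g <- default_growth()
  expect_equal(pdu_rhs(5, rep(0, 15), p, g)[[1]], rep(0, 15))
  expect_equal(wellmixed_rhs(5, rep(0, 10), p, g)[[1]], rep(0, 10))
})

test_that("pure transport conserves weighted totals per species", {
  p <- transport_only_params()
  g <- flat_growth(5e8)
  rho <- 5e8 / 1e12
  Vl <- p$compartments$total_volume_um3
  Vcomp <- p$compartments$geometry$volume_per_compartment_um3
  Vcyt <- cytosol_volume(p)
  set.seed(7)
  for (i in 1:10) {
    y <- runif(15, 0, 60)
    d <- pdu_rhs(3, y, p, g)[[1]]
    for (s in 1:5) {
      # d/dt of rho*(V_lum*c_lum + V_cyt*c_cyt) + c_ext must vanish
      tot <- rho * (Vl * d[s] + Vcyt * d[5 + s]) + d[10 + s]
      expect_equal(tot, 0, tolerance = 1e-10)
    }
  }
})

test_that("transport-only start from external PDO moves mass conservatively", {
  p <- transport_only_params()
  g <- flat_growth()
  y <- rep(0, 15); y[11] <- 55
  d <- pdu_rhs(0, y, p, g)[[1]]
  expect_lt(d[11], 0)      # external PDO decreases
  expect_gt(d[6], 0)       # cytosolic PDO increases
  expect_equal(d[12:15], rep(0, 4))  # other external species untouched
})

test_that("compiled and R engines integrate to the same trajectories", {
  p <- pdu_model_parameters()
  g <- default_growth()
  a <- run_simulation(p, g, t_span = c(0, 20))
  b <- run_simulation(p, g, t_span = c(0, 20), engine = "R")
  rel <- apply(abs(a$state - b$state), 2, max) /
    pmax(apply(abs(b$state), 2, max), 1e-9)
  expect_lt(max(rel), 1e-3)
})
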