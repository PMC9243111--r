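test_that("sphere geometry matches the closed-form area and volume", {
  g <- make_sphere(140)
  r <- 0.07 # um
  expect_equal(g$area_per_compartment_um2, 4 * pi * r^2)
  expect_equal(g$volume_per_compartment_um3, 4 / 3 * pi * r^3)
  expect_equal(g$area_per_compartment_um2, 6.157522e-2, tolerance = 1e-6)
  expect_equal(g$volume_per_compartment_um3, 1.436755e-3, tolerance = 1e-6)

  unit <- make_sphere(2) # unit radius in nm
  expect_equal(unit$area_per_compartment_um2, 4 * pi * 1e-6)
  expect_equal(unit$volume_per_compartment_um3, 4 / 3 * pi * 1e-9)

  expect_error(make_sphere(0), "positive")
  expect_error(make_sphere(-1), "positive")
})

test_that("cylinder geometry is lateral-only unless end caps are included", {
  g <- make_cylinder(50, 2500)
  expect_equal(g$area_per_compartment_um2, 2 * pi * 0.025 * 2.5)
  expect_equal(g$area_per_compartment_um2, 0.3926991, tolerance = 1e-6)
  expect_equal(g$volume_per_compartment_um3, pi * 0.025^2 * 2.5)
  expect_equal(g$volume_per_compartment_um3, 4.908739e-3, tolerance = 1e-6)

  ge <- make_cylinder(50, 2500, include_end_area = TRUE)
  expect_equal(ge$area_per_compartment_um2,
               g$area_per_compartment_um2 + 2 * pi * 0.025^2)
  expect_equal(ge$end_area_um2, 3.926991e-3, tolerance = 1e-6)

  expect_error(make_cylinder(50, 0), "positive")
  expect_error(make_cylinder(0, 2500), "positive")
})

test_that("capsule cell geometry and cytosol-volume guard", {
  cg <- cell_geometry(0.5, 2.5)
  expect_equal(cg$cell_volume_um3, pi * 0.25 * 1.5 + 4 / 3 * pi * 0.125)
  expect_equal(cg$membrane_area_um2, 2 * pi * 0.5 * 1.5 + 4 * pi * 0.25)
  expect_error(cell_geometry(0.5, 0.9), "length")
  # compartments cannot exceed the cell volume
  big <- compartment_ensemble(make_sphere(140), 5000)
  expect_error(pdu_model_parameters(compartments = big), "exceeds")
})

test_that("ensemble matching reproduces the printed 1.9-fold factors", {
  base <- compartment_ensemble(make_sphere(140), 15)
  cyl <- make_cylinder(50, 2500)

  ev <- match_ensemble(base, cyl, "equal_volume")
  expect_equal(ev$count, 4.390400, tolerance = 1e-4)
  expect_equal(ev$total_volume_um3, base$total_volume_um3)
  fold_area <- ev$total_area_um2 / base$total_area_um2
  expect_equal(fold_area, sa_v_fold_factor(70, 25))
  expect_equal(signif(fold_area, 2), 1.9)

  ea <- match_ensemble(base, cyl, "equal_area")
  expect_equal(ea$count, 2.352, tolerance = 1e-3)
  expect_equal(ea$total_area_um2, base$total_area_um2)
  fold_conc <- base$total_volume_um3 / ea$total_volume_um3
  expect_equal(fold_conc, sa_v_fold_factor(70, 25))
  expect_equal(signif(fold_conc, 2), 1.9)

  fc <- match_ensemble(base, base$geometry, "fixed_count", count = base$count)
  expect_equal(fc$total_area_um2, base$total_area_um2)
  expect_equal(fc$total_volume_um3, base$total_volume_um3)
  expect_error(match_ensemble(base, cyl, "fixed_count"), "count")
})

test_that("fold factors agree with the analytic oracle for arbitrary radii", {
  expect_equal(sa_v_fold_factor(70, 25), 2 * 70 / (3 * 25))
  expect_equal(sa_v_fold_factor(3, 2), 1.0)
  expect_equal(sa_v_fold_factor(1.5 * 7, 7), 1.0)
  expect_error(sa_v_fold_factor(-1, 2), "positive")

  set.seed(42)
  for (i in 1:20) {
    rs <- runif(1, 10, 200)
    rc <- runif(1, 5, 100)
    L <- runif(1, 500, 5000)
    base <- compartment_ensemble(make_sphere(2 * rs), runif(1, 1, 40))
    cyl <- make_cylinder(2 * rc, L)
    ev <- match_ensemble(base, cyl, "equal_volume")
    ea <- match_ensemble(base, cyl, "equal_area")
    area_fold <- ev$total_area_um2 / base$total_area_um2
    vol_fold <- ea$total_volume_um3 / base$total_volume_um3
    expect_equal(area_fold, sa_v_fold_factor(rs, rc), tolerance = 1e-12)
    # equal-area volume fold is the reciprocal of the equal-volume area fold
    expect_equal(area_fold * vol_fold, 1, tolerance = 1e-12)
  }
})
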