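test_that("growth model validation and evaluation", {
  expect_error(growth_model(td_early_h = 10, td_late_h = 3), "slow")
  gm <- growth_model()
  expect_equal(growth_model_density(gm, 0), gm$n0_cells_ml)
  # continuity at the phase joins
  eps <- 1e-9
  for (tj in c(gm$lag_h, gm$t_switch_h)) {
    expect_equal(growth_model_density(gm, tj - eps),
                 growth_model_density(gm, tj + eps), tolerance = 1e-6)
  }
})

test_that("noiseless generation equals the forward model on the grid", {
  truth <- pdu_model_parameters()
  ds <- generate_dataset(truth, growth_model(),
                         noise_model(cv = 0, detection_floor_mM = 0,
                                     replicates = 2))
  for (r in 1:2) {
    m <- ds$measurements[ds$measurements$replicate == r &
                           ds$measurements$species == "PDO", ]
    ser <- concentration_series(ds$sim, "external", "PDO")
    expect_equal(m$concentration_mM,
                 approx(ser$time_h, ser$concentration_mM, m$time_h)$y)
  }
})

test_that("generation is seed-deterministic and censoring is clean", {
  truth <- pdu_model_parameters()
  a <- generate_dataset(truth, noise = noise_model(seed = 17))
  b <- generate_dataset(truth, noise = noise_model(seed = 17))
  expect_identical(a$measurements, b$measurements)
  c2 <- generate_dataset(truth, noise = noise_model(seed = 18))
  expect_false(identical(a$measurements, c2$measurements))
  expect_true(all(a$measurements$concentration_mM >= 0))
  obs <- a$measurements$concentration_mM
  expect_true(all(obs == 0 | obs >= a$noise$detection_floor_mM))
})

test_that("replicate scatter reproduces the nominal coefficient of variation", {
  truth <- pdu_model_parameters()
  cvs <- c()
  for (seed in 1:10) {
    ds <- generate_dataset(truth,
                           noise = noise_model(cv = 0.05, seed = seed,
                                               detection_floor_mM = 0))
    m <- ds$measurements
    for (sp in unique(m$species)) {
      w <- m[m$species == sp, ]
      mat <- matrix(w$concentration_mM, ncol = max(w$replicate))
      mu <- rowMeans(mat)
      keep <- mu > 5 # well above zero so the ratio is stable
      if (any(keep)) {
        cvs <- c(cvs, (apply(mat, 1, sd) / mu)[keep])
      }
    }
  }
  expect_equal(mean(cvs), 0.05, tolerance = 0.30)
})

test_that("datasets round-trip exactly through the CSV writer", {
  truth <- pdu_model_parameters()
  ds <- generate_dataset(truth, noise = noise_model(cv = 0, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_timeseries(ds, path)
  back <- read_timeseries(path)
  expect_equal(back$concentration_mM, ds$measurements$concentration_mM)
  expect_equal(back$time_h, ds$measurements$time_h)
  expect_identical(back$species, ds$measurements$species)
})
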