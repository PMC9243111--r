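#' Synthetic growth curves and metabolite datasets
#'
#' Stand-ins for the study-style measurements: an OD-derived growth curve
#' with an early fast phase and a late slow phase, and replicate external
#' metabolite time series with multiplicative HPLC-style noise and a
#' detection floor. The generator stores the true parameters alongside the
#' data so parameter-recovery studies can be scored.
#'
#' @name synthetic
NULL

#' Piecewise-exponential growth model
#'
#' Density is constant during the lag, grows exponentially with doubling
#' time `td_early_h` until `t_switch_h`, then with `td_late_h`; the curve is
#' continuous at the joins. Defaults emulate wild-type growth on
#' 1,2-propanediol: doubling time 3.17 h in the 3-9 h window slowing to
#' 9.2 h in the 12-18 h window as the aldehyde intermediate builds up.
#'
#' @param n0_cells_ml Initial density (default 5e7 cells/mL, a light
#'   inoculum).
#' @param lag_h Lag duration, h (default 1).
#' @param td_early_h Early doubling time, h (default 3.17).
#' @param t_switch_h Time of the growth-rate switch, h (default 12).
#' @param td_late_h Late doubling time, h (default 9.2); must be >=
#'   `td_early_h` (growth slows).
#' @return A `growth_model` object.
#' @export
growth_model <- function(n0_cells_ml = 5e7, lag_h = 1, td_early_h = 3.17,
                         t_switch_h = 12, td_late_h = 9.2) {
  stopifnot(n0_cells_ml > 0, lag_h >= 0, td_early_h > 0, td_late_h > 0,
            t_switch_h > lag_h)
  if (td_early_h > td_late_h) {
    stop("growth must slow down: td_early_h <= td_late_h", call. = FALSE)
  }
  structure(list(n0_cells_ml = n0_cells_ml, lag_h = lag_h,
                 td_early_h = td_early_h, t_switch_h = t_switch_h,
                 td_late_h = td_late_h),
            class = "growth_model")
}

#' Evaluate a piecewise-exponential growth model
#'
#' @param model A `growth_model`.
#' @param t Times, h.
#' @return Cell density, cells/mL.
#' @export
growth_model_density <- function(model, t) {
  stopifnot(inherits(model, "growth_model"))
  t1 <- pmin(pmax(t - model$lag_h, 0), model$t_switch_h - model$lag_h)
  t2 <- pmax(t - model$t_switch_h, 0)
  model$n0_cells_ml * 2^(t1 / model$td_early_h) * 2^(t2 / model$td_late_h)
}

#' Sample a growth model into a growth curve
#'
#' @param model A `growth_model`.
#' @param sampling_times_h Sample times, h (default hourly over 0-30 h; the
#'   interpolation contract of [growth_curve()] reproduces the model exactly
#'   between samples away from the phase joins).
#' @return A `growth_curve`.
#' @export
generate_growth_curve <- function(model, sampling_times_h = seq(0, 30, by = 1)) {
  tt <- sort(unique(c(sampling_times_h, model$lag_h, model$t_switch_h)))
  tt <- tt[tt >= min(sampling_times_h) & tt <= max(sampling_times_h)]
  growth_curve(tt, growth_model_density(model, tt))
}

#' HPLC-style measurement noise model
#'
#' Multiplicative lognormal noise (relative error of the assay), a detection
#' floor below which values are reported as 0, sampling every 3 h over the
#' 30 h experiment, and 3 biological replicates. The floor and coefficient
#' of variation are design defaults chosen below the 5 mM bottom of the
#' calibration-standard range.
#'
#' @param cv Relative standard deviation of the multiplicative noise
#'   (default 0.05).
#' @param detection_floor_mM Values below this are reported as 0
#'   (default 0.5).
#' @param sampling_times_h Sampling grid, h (default `seq(0, 30, 3)`).
#' @param replicates Number of replicates (default 3).
#' @param seed Master integer seed (default 1).
#' @return A `noise_model` object.
#' @export
noise_model <- function(cv = 0.05, detection_floor_mM = 0.5,
                        sampling_times_h = seq(0, 30, by = 3),
                        replicates = 3L, seed = 1L) {
  stopifnot(cv >= 0, detection_floor_mM >= 0, replicates >= 1)
  structure(list(cv = cv, detection_floor_mM = detection_floor_mM,
                 sampling_times_h = sampling_times_h,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic external-metabolite dataset
#'
#' Runs the forward model at the true parameters, samples the external
#' concentrations of the four measured metabolites (1,2-propanediol,
#' propionaldehyde, 1-propanol, propionate) on the noise model's grid,
#' multiplies by lognormal noise exp(e), e ~ Normal(0, cv), and censors
#' values below the detection floor to 0. Replicate seeds are derived
#' deterministically from the master seed, so identical seeds give
#' identical datasets.
#'
#' @param truth A `pdu_params` used as ground truth.
#' @param growth_model_obj A `growth_model`.
#' @param noise A `noise_model`.
#' @param ... Passed to [run_simulation()].
#' @return A `synthetic_dataset`: `growth` (a `growth_curve`),
#'   `measurements` (tidy data frame: replicate, time_h, species,
#'   concentration_mM), `truth`, `noise`, and the noiseless `sim`.
#' @export
generate_dataset <- function(truth, growth_model_obj = growth_model(),
                             noise = noise_model(), ...) {
  stopifnot(inherits(truth, "pdu_params"), inherits(noise, "noise_model"),
            inherits(growth_model_obj, "growth_model"))
  growth <- generate_growth_curve(growth_model_obj)
  tmax <- max(noise$sampling_times_h)
  sim <- run_simulation(truth, growth, t_span = c(0, tmax), ...)
  measured <- c("PDO", "PALD", "POH", "PROP")
  clean <- sapply(measured, function(s) {
    ser <- concentration_series(sim, "external", s)
    stats::approx(ser$time_h, ser$concentration_mM,
                  xout = noise$sampling_times_h)$y
  })
  reps <- lapply(seq_len(noise$replicates), function(r) {
    ## replicate-specific stream derived from the master seed
    set.seed(noise$seed * 1000L + r)
    eps <- matrix(stats::rnorm(length(clean), sd = noise$cv), nrow = nrow(clean))
    obs <- clean * exp(eps)
    obs[obs < noise$detection_floor_mM] <- 0
    data.frame(
      replicate = r,
      time_h = rep(noise$sampling_times_h, times = length(measured)),
      species = rep(measured, each = length(noise$sampling_times_h)),
      concentration_mM = as.vector(obs),
      stringsAsFactors = FALSE)
  })
  structure(
    list(growth = growth, measurements = do.call(rbind, reps),
         truth = truth, noise = noise, sim = sim),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d replicates x %d times, cv = %g, floor = %g mM>\n",
              x$noise$replicates, length(x$noise$sampling_times_h),
              x$noise$cv, x$noise$detection_floor_mM))
  invisible(x)
}
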