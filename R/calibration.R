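#' Calibration against timescale and toxicity criteria
#'
#' The base spherical-compartment model is parameterized by adjusting the
#' shell permeability and the PduP/PduQ maximal rates until (1) external
#' 1,2-propanediol is depleted on the experimentally observed timescale,
#' (2) external propionate and 1-propanol first appear around 10 h, and
#' (3) the propionaldehyde maximum stays below the concentration reported
#' to cause strong growth defects (16 mM).
#'
#' @name calibration
NULL

#' Calibration target set
#'
#' @param pdo_depletion_window Window (h) in which external
#'   1,2-propanediol should fall below 1% of its initial value
#'   (default `c(10, 20)`).
#' @param onset_time_target_h Target first-appearance time of external
#'   propionate and 1-propanol (default 10).
#' @param onset_tolerance_h Acceptance half-width on the onset time
#'   (default 1).
#' @param pald_peak_ceiling_mM Maximum admissible propionaldehyde
#'   concentration (default 16).
#' @param pald_onset_target_h Optional target first-appearance time of
#'   external propionaldehyde (default `NA`, off). This encodes the aldehyde
#'   *buildup* timescale; note that the criteria under-determine the free
#'   parameters either way (see the methods vignette on objective
#'   degeneracy).
#' @param peak_region Region whose propionaldehyde maximum the ceiling
#'   constrains; default `"cytosol"` (the toxicity-relevant pool), with
#'   `"external"` and `"lumen"` available.
#' @param onset_threshold_mM Concentration defining "first appearance"
#'   (default 1).
#' @return A `calibration_targets` object.
#' @export
calibration_targets <- function(pdo_depletion_window = c(10, 20),
                                onset_time_target_h = 10,
                                onset_tolerance_h = 1,
                                pald_peak_ceiling_mM = 16,
                                pald_onset_target_h = NA_real_,
                                peak_region = c("cytosol", "external", "lumen"),
                                onset_threshold_mM = 1) {
  stopifnot(length(pdo_depletion_window) == 2L,
            pdo_depletion_window[1] < pdo_depletion_window[2],
            pald_peak_ceiling_mM > 0, onset_tolerance_h > 0,
            onset_threshold_mM > 0)
  structure(list(pdo_depletion_window = pdo_depletion_window,
                 onset_time_target_h = onset_time_target_h,
                 onset_tolerance_h = onset_tolerance_h,
                 pald_peak_ceiling_mM = pald_peak_ceiling_mM,
                 pald_onset_target_h = pald_onset_target_h,
                 peak_region = match.arg(peak_region),
                 onset_threshold_mM = onset_threshold_mM),
            class = "calibration_targets")
}

#' Evaluate the calibration criteria for one parameter set
#'
#' @param params A `pdu_params`.
#' @param targets A `calibration_targets`.
#' @param growth A `growth_curve`.
#' @param ... Passed to [run_simulation()].
#' @return List with the summary statistics (`pdo_depletion_h`,
#'   `prop_onset_h`, `poh_onset_h`, `pald_peak_mM`) and logical
#'   `constraints_satisfied` per criterion.
#' @export
evaluate_targets <- function(params, targets, growth, ...) {
  sim <- run_simulation(params, growth, ...)
  pdo <- concentration_series(sim, "external", "PDO")
  pald <- concentration_series(sim, targets$peak_region, "PALD")
  stats <- list(
    pdo_depletion_h = depletion_time(pdo$time_h, pdo$concentration_mM),
    prop_onset_h = onset_time_of(sim, "PROP", targets$onset_threshold_mM),
    poh_onset_h = onset_time_of(sim, "POH", targets$onset_threshold_mM),
    pald_onset_h = onset_time_of(sim, "PALD", targets$onset_threshold_mM),
    pald_peak_mM = unname(peak(pald$time_h, pald$concentration_mM)["c_peak"]))
  w <- targets$pdo_depletion_window
  ok <- c(
    depletion_in_window = !is.na(stats$pdo_depletion_h) &&
      stats$pdo_depletion_h >= w[1] && stats$pdo_depletion_h <= w[2],
    prop_onset = !is.na(stats$prop_onset_h) &&
      abs(stats$prop_onset_h - targets$onset_time_target_h) <=
        targets$onset_tolerance_h,
    poh_onset = !is.na(stats$poh_onset_h) &&
      abs(stats$poh_onset_h - targets$onset_time_target_h) <=
        targets$onset_tolerance_h,
    pald_peak = stats$pald_peak_mM <= targets$pald_peak_ceiling_mM)
  c(stats, list(constraints_satisfied = ok))
}

calibration_objective <- function(stats, targets) {
  w <- targets$pdo_depletion_window
  mid <- mean(w)
  dep <- stats$pdo_depletion_h
  onP <- stats$prop_onset_h
  onH <- stats$poh_onset_h
  if (is.na(dep)) dep <- 2 * w[2]      # never depleted: penalize far out
  if (is.na(onP)) onP <- 3 * targets$onset_time_target_h
  if (is.na(onH)) onH <- 3 * targets$onset_time_target_h
  obj <- (dep - mid)^2 +
    (onP - targets$onset_time_target_h)^2 +
    (onH - targets$onset_time_target_h)^2 +
    100 * max(0, stats$pald_peak_mM - targets$pald_peak_ceiling_mM)^2
  if (!is.na(targets$pald_onset_target_h)) {
    onA <- stats$pald_onset_h
    if (is.na(onA)) onA <- 3 * targets$pald_onset_target_h
    obj <- obj + (onA - targets$pald_onset_target_h)^2
  }
  obj
}

free_name_map <- c(k_c = "k_c", vmax_P = "vmax_P", vmax_Q = "vmax_Q")

#' Calibrate shell permeability and PduP/PduQ activities
#'
#' Two-stage deterministic search over the free parameters: a coarse grid of
#' 7 log-spaced points per parameter spanning two decades either side of the
#' current values, followed by derivative-free local refinement
#' (Nelder-Mead on log10 parameters) of a penalty objective — squared
#' distance of the depletion time to the window midpoint, squared onset-time
#' errors, and a hinge penalty on the propionaldehyde peak above the
#' ceiling. The coarse stage integrates at slightly relaxed tolerances for
#' speed; the returned point is re-evaluated at the defaults.
#'
#' @param params Starting `pdu_params` (also the grid centre).
#' @param targets A `calibration_targets`.
#' @param growth A `growth_curve`.
#' @param free Character subset of `c("k_c", "vmax_P", "vmax_Q")`; empty for
#'   evaluation only.
#' @param grid_points Grid points per free parameter (default 7).
#' @param grid_decades Half-width of the grid in decades (default 2).
#' @param refine_maxit Nelder-Mead iteration cap (default 60).
#' @param ... Passed to [run_simulation()] in the final evaluations.
#' @return A `calibration_result`: `params` (calibrated), `fitted` (named
#'   values of the free parameters), `objective_value`, `stats`,
#'   `constraints_satisfied`, and the `search_trace` data frame.
#' @export
calibrate <- function(params, targets = calibration_targets(), growth,
                      free = c("k_c", "vmax_P", "vmax_Q"),
                      grid_points = 7, grid_decades = 2,
                      refine_maxit = 60, ...) {
  stopifnot(inherits(params, "pdu_params"),
            inherits(targets, "calibration_targets"))
  if (!all(free %in% names(free_name_map))) {
    stop("free parameters must be a subset of ",
         paste(names(free_name_map), collapse = ", "), call. = FALSE)
  }
  if (length(free) == 0L) {
    st <- evaluate_targets(params, targets, growth, ...)
    return(structure(list(params = params, fitted = numeric(0),
                          objective_value = calibration_objective(st, targets),
                          stats = st[names(st) != "constraints_satisfied"],
                          constraints_satisfied = st$constraints_satisfied,
                          search_trace = NULL),
                     class = "calibration_result"))
  }
  start <- vapply(free, function(f) param_value(params, f), 0)
  apply_point <- function(logvals) {
    p <- params
    for (i in seq_along(free)) p <- set_param(p, free[i], 10^logvals[i])
    p
  }
  eval_point <- function(logvals, fast = TRUE) {
    p <- apply_point(logvals)
    st <- tryCatch(
      if (fast) evaluate_targets(p, targets, growth, rtol = 1e-6, atol = 1e-8)
      else evaluate_targets(p, targets, growth, ...),
      error = function(e) NULL)
    if (is.null(st)) return(list(obj = 1e8, stats = NULL))
    list(obj = calibration_objective(st, targets), stats = st)
  }
  ## stage 1: coarse grid
  axes <- lapply(start, function(v) {
    log10(v) + seq(-grid_decades, grid_decades, length.out = grid_points)
  })
  grid <- as.matrix(expand.grid(axes))
  trace <- data.frame(stage = character(0), objective = numeric(0))
  objs <- apply(grid, 1, function(g) eval_point(g)$obj)
  trace <- data.frame(stage = rep("grid", nrow(grid)),
                      objective = objs)
  best <- which.min(objs)
  ## stage 2: local refinement from the best grid point
  opt <- if (length(free) == 1L) {
    step <- if (grid_points > 1) 2 * grid_decades / (grid_points - 1) else 0.5
    o <- stats::optimize(function(v) eval_point(v)$obj,
                         grid[best, 1] + c(-step, step), tol = 1e-4)
    list(par = o$minimum, value = o$objective)
  } else {
    stats::optim(grid[best, ], function(g) eval_point(g)$obj,
                 method = "Nelder-Mead",
                 control = list(maxit = refine_maxit, reltol = 1e-4))
  }
  trace <- rbind(trace, data.frame(stage = "refine", objective = opt$value))
  final <- eval_point(opt$par, fast = FALSE)
  p_fin <- apply_point(opt$par)
  st <- final$stats
  if (is.null(st)) stop("calibration failed: refined point not integrable",
                        call. = FALSE)
  if (!all(st$constraints_satisfied)) {
    miss <- st[names(st) != "constraints_satisfied"]
    stop("no feasible calibration found; nearest miss: ",
         paste(sprintf("%s=%.3g", names(miss), unlist(miss)),
               collapse = ", "),
         " (unsatisfied: ",
         paste(names(which(!st$constraints_satisfied)), collapse = ", "), ")",
         call. = FALSE)
  }
  structure(list(params = p_fin,
                 fitted = stats::setNames(10^opt$par, free),
                 objective_value = final$obj,
                 stats = st[names(st) != "constraints_satisfied"],
                 constraints_satisfied = st$constraints_satisfied,
                 search_trace = trace),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  if (length(x$fitted)) {
    cat("  fitted:", paste(sprintf("%s = %.4g", names(x$fitted), x$fitted),
                           collapse = ", "), "\n")
  }
  cat(sprintf("  objective %.4g; constraints %s\n", x$objective_value,
              if (all(x$constraints_satisfied)) "satisfied"
              else paste("violated:",
                         paste(names(which(!x$constraints_satisfied)),
                               collapse = ", "))))
  for (nmi in names(x$stats)) {
    cat(sprintf("  %s = %.4g\n", nmi, x$stats[[nmi]]))
  }
  invisible(x)
}

#' Least-squares fit of model parameters to observed time series
#'
#' Weighted least squares between the model's external concentrations and a
#' tidy table of observations (columns `time_h`, `species`,
#' `concentration_mM`, optionally `replicate`). With `loss = "sse"`,
#' residuals are normalized by the initial external 1,2-propanediol so all
#' species contribute on a common scale; `loss = "log_sse"` compares
#' log(c + 1 mM). Optimization is derivative-free (Nelder-Mead on log10
#' parameters), hence deterministic.
#'
#' @param params Starting `pdu_params`.
#' @param observed Tidy observation table.
#' @param growth A `growth_curve`.
#' @param free Character vector of parameter names (see
#'   [perturbable_parameters()]).
#' @param loss `"sse"` or `"log_sse"`.
#' @param maxit Nelder-Mead iteration cap (default 200).
#' @param ... Passed to [run_simulation()].
#' @return A `calibration_result` with `fitted`, `objective_value`,
#'   `params`, and `search_trace`.
#' @export
fit_to_timeseries <- function(params, observed, growth, free,
                              loss = c("sse", "log_sse"), maxit = 200, ...) {
  stopifnot(inherits(params, "pdu_params"), is.data.frame(observed),
            all(c("time_h", "species", "concentration_mM") %in% names(observed)),
            nrow(observed) > 0, length(free) >= 1)
  loss <- match.arg(loss)
  bad <- setdiff(unique(observed$species), SPECIES)
  if (length(bad)) {
    stop("observed species not in the model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(free %in% perturbable_parameters())) {
    stop("unknown free parameter(s): ",
         paste(setdiff(free, perturbable_parameters()), collapse = ", "),
         call. = FALSE)
  }
  tmax <- max(observed$time_h)
  scale0 <- params$initial_external_PDO_mM
  objective <- function(logvals) {
    p <- params
    for (i in seq_along(free)) p <- set_param(p, free[i], 10^logvals[i])
    sim <- tryCatch(run_simulation(p, growth, t_span = c(0, tmax),
                                   rtol = 1e-6, atol = 1e-8, ...),
                    error = function(e) NULL)
    if (is.null(sim)) return(1e8)
    err <- 0
    for (s in unique(observed$species)) {
      o <- observed[observed$species == s, ]
      ser <- concentration_series(sim, "external", s)
      m <- stats::approx(ser$time_h, ser$concentration_mM, xout = o$time_h,
                         rule = 2)$y
      err <- err + if (loss == "sse") {
        sum(((m - o$concentration_mM) / scale0)^2)
      } else {
        sum((log(m + 1) - log(o$concentration_mM + 1))^2)
      }
    }
    err
  }
  start <- log10(vapply(free, function(f) param_value(params, f), 0))
  opt <- if (length(free) == 1L) {
    ## one-dimensional: golden-section-safe optimize over +/- 2 decades
    o <- stats::optimize(function(v) objective(v), start + c(-2, 2),
                         tol = 1e-4)
    list(par = o$minimum, value = o$objective,
         counts = NA_integer_)
  } else {
    stats::optim(start, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
  }
  p_fin <- params
  for (i in seq_along(free)) p_fin <- set_param(p_fin, free[i], 10^opt$par[i])
  structure(list(params = p_fin,
                 fitted = stats::setNames(10^opt$par, free),
                 objective_value = opt$value,
                 stats = NULL,
                 constraints_satisfied = NULL,
                 search_trace = data.frame(stage = "optimize",
                                           objective = opt$value)),
            class = "calibration_result")
}
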