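#' Integrating the model and comparing geometries
#'
#' @name simulation
NULL

state_names <- function(model) {
  regions <- if (model == "wellmixed") REGIONS[2:3] else REGIONS
  as.vector(t(outer(regions, SPECIES, paste, sep = ".")))
}

forcing_matrices <- function(growth, t_span, dilute_by_growth) {
  tf <- sort(unique(c(t_span, growth$times_h[growth$times_h > t_span[1] &
                                               growth$times_h < t_span[2]])))
  logn <- cbind(tf, log(growth_density(growth, tf)))
  ## growth rate sampled densely so that the step at phase changes is
  ## resolved by the solver's linear forcing interpolation
  tmu <- sort(unique(c(tf, seq(t_span[1], t_span[2], by = 0.05))))
  muv <- if (dilute_by_growth) growth_log_slope(growth, tmu) else 0 * tmu
  list(logn = logn, mu = cbind(tmu, muv))
}

#' Run the pathway simulation
#'
#' Integrates the three-region system (or its well-mixed limit) with a
#' stiff-capable solver (`deSolve::lsoda`) from a zero state except for the
#' initial external 1,2-propanediol. The compiled right-hand side is used by
#' default; `engine = "R"` integrates the reference R implementation
#' ([pdu_rhs()] / [wellmixed_rhs()]) instead, which is bitwise-comparable on
#' small problems and used for cross-checking.
#'
#' @param params A `pdu_params`.
#' @param growth A `growth_curve`.
#' @param t_span Two-element time span in hours (default `c(0, 30)`,
#'   mirroring the experimental horizon).
#' @param output_dt Output grid spacing, h (default 0.1).
#' @param model `"compartmentalized"` (15 states) or `"wellmixed"` (10
#'   states, the broken-compartment limit).
#' @param engine `"compiled"` or `"R"`.
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10).
#' @param dilute_by_growth Apply the intracellular growth-dilution term
#'   (default `TRUE`; see [pdu_rhs()]).
#' @return A `pdu_sim` object: `times`, `state` (matrix time x species,
#'   columns named `region.species`), the inputs, and solver diagnostics
#'   including the carbon-conservation residual.
#' @export
run_simulation <- function(params, growth, t_span = c(0, 30), output_dt = 0.1,
                           model = c("compartmentalized", "wellmixed"),
                           engine = c("compiled", "R"),
                           rtol = 1e-8, atol = 1e-10,
                           dilute_by_growth = TRUE) {
  stopifnot(inherits(params, "pdu_params"), inherits(growth, "growth_curve"),
            length(t_span) == 2L, t_span[1] < t_span[2], output_dt > 0)
  model <- match.arg(model)
  engine <- match.arg(engine)
  if (cytosol_volume(params) <= 0) {
    stop("cytosol volume must be positive", call. = FALSE)
  }
  times <- seq(t_span[1], t_span[2], by = output_dt)
  nm <- state_names(model)
  y0 <- stats::setNames(rep(0, length(nm)), nm)
  y0[paste0("external.", "PDO")] <- params$initial_external_PDO_mM

  if (engine == "compiled") {
    k <- rhs_constants(params)
    parms <- c(k$kA_comp, k$V_comp, k$count, k$V_cyt, k$kmA_cell, k$mem,
               k$vC, k$kmC, k$vP, k$kmP, k$vPr, k$kmPr,
               k$vQ, k$kmQ, k$vQr, k$kmQr, k$vL, k$kmL)
    fm <- forcing_matrices(growth, t_span, dilute_by_growth)
    out <- deSolve::lsoda(
      y = y0, times = times, parms = parms,
      func = if (model == "wellmixed") "pdu_derivs_wm" else "pdu_derivs",
      dllname = "pdukinetics", initfunc = "pdu_initmod",
      initforc = "pdu_initforc", forcings = fm,
      fcontrol = list(method = "linear", rule = 2),
      rtol = rtol, atol = atol)
  } else {
    fn <- if (model == "wellmixed") wellmixed_rhs else pdu_rhs
    out <- deSolve::lsoda(
      y = y0, times = times,
      func = function(t, y, p) fn(t, y, params, growth, dilute_by_growth),
      parms = NULL, rtol = rtol, atol = atol)
  }
  diagn <- attributes(out)
  success <- is.null(diagn$istate) || diagn$istate[1] >= 0
  if (!success || nrow(out) < length(times)) {
    stop("ODE integration failed (istate = ",
         paste(diagn$istate, collapse = ","), ")", call. = FALSE)
  }
  state <- out[, -1, drop = FALSE]
  colnames(state) <- nm
  res <- structure(
    list(times = times, state = state, growth = growth, params = params,
         model = model, engine = engine,
         diagnostics = list(rtol = rtol, atol = atol,
                            steps = unname(diagn$istate[3]),
                            success = TRUE,
                            dilute_by_growth = dilute_by_growth)),
    class = "pdu_sim")
  res$diagnostics$conservation_residual <- conservation_residual(res)
  if (is.finite(res$diagnostics$conservation_residual) &&
      res$diagnostics$conservation_residual > 0.005) {
    warning(sprintf("carbon-conservation residual %.3g exceeds 0.5%%",
                    res$diagnostics$conservation_residual))
  }
  res
}

#' Volume- and cell-number-weighted species totals
#'
#' Totals are expressed as external-medium-equivalent concentrations (mM):
#' `rho(t) * (V_lumen_total * c_lumen + V_cyt * c_cyt) + c_ext` per species,
#' with `rho` the cell density per um^3 of medium. With growth dilution
#' enabled these totals change only through reactions; their sum over the
#' five species (the carbon skeleton) is constant.
#'
#' @param sim A `pdu_sim`.
#' @return Matrix time x species of weighted totals, mM.
#' @export
species_totals <- function(sim) {
  stopifnot(inherits(sim, "pdu_sim"))
  p <- sim$params
  rho <- growth_density(sim$growth, sim$times) / 1e12
  Vl <- p$compartments$total_volume_um3
  Vc <- cytosol_volume(p)
  tot <- sapply(SPECIES, function(s) {
    ext <- sim$state[, paste0("external.", s)]
    cyt <- sim$state[, paste0("cytosol.", s)]
    lum <- if (sim$model == "wellmixed") 0 else sim$state[, paste0("lumen.", s)]
    rho * (Vl * lum + Vc * cyt) + ext
  })
  colnames(tot) <- SPECIES
  tot
}

conservation_residual <- function(sim) {
  tot <- rowSums(species_totals(sim))
  if (tot[1] <= 0) return(NA_real_)
  max(abs(tot - tot[1])) / tot[1]
}

#' @export
print.pdu_sim <- function(x, ...) {
  cat(sprintf("<pdu_sim: %s, %d time points over [%g, %g] h, engine %s>\n",
              x$model, length(x$times), min(x$times), max(x$times), x$engine))
  cat(sprintf("  conservation residual %.3g\n",
              x$diagnostics$conservation_residual))
  invisible(x)
}

#' Tidy trajectory table
#'
#' @param x A `pdu_sim`.
#' @param ... Unused.
#' @return Data frame with columns `time_h`, `region`, `species`,
#'   `concentration_mM`.
#' @export
as.data.frame.pdu_sim <- function(x, ...) {
  nm <- colnames(x$state)
  parts <- strsplit(nm, ".", fixed = TRUE)
  data.frame(
    time_h = rep(x$times, times = length(nm)),
    region = rep(vapply(parts, `[`, "", 1L), each = length(x$times)),
    species = rep(vapply(parts, `[`, "", 2L), each = length(x$times)),
    concentration_mM = as.vector(x$state),
    stringsAsFactors = FALSE)
}

#' Extract one concentration series
#'
#' @param sim A `pdu_sim`.
#' @param region One of `"lumen"`, `"cytosol"`, `"external"`.
#' @param species One of `"PDO"`, `"PALD"`, `"PCOA"`, `"POH"`, `"PROP"`.
#' @return Data frame with `time_h` and `concentration_mM`.
#' @export
concentration_series <- function(sim, region, species) {
  stopifnot(inherits(sim, "pdu_sim"))
  region <- match.arg(region, REGIONS)
  species <- match.arg(species, SPECIES)
  col <- paste0(region, ".", species)
  if (!col %in% colnames(sim$state)) {
    stop("region '", region, "' not present in this model", call. = FALSE)
  }
  data.frame(time_h = sim$times, concentration_mM = unname(sim$state[, col]))
}

#' Simulate the microcompartment base case against microtube limits
#'
#' Re-runs the model with the compartment ensemble replaced by cylinders
#' matched to the base ensemble by equal total volume and/or equal total
#' surface area, all non-geometric parameters identical (under
#' `fixed_total_enzyme` the equal-area case concentrates the same enzymes
#' into less volume). Returns the external-metabolite overlay and summary
#' statistics per scenario.
#'
#' @param base_params A `pdu_params` (typically the spherical base case).
#' @param modes Character subset of `c("equal_volume", "equal_area")`; empty
#'   for a base-only table.
#' @param growth A `growth_curve`.
#' @param mt_diameter_nm Microtube diameter, nm (default 50).
#' @param onset_threshold_mM Threshold for onset summaries (default 1).
#' @param ... Passed to [run_simulation()].
#' @return List with `summary` (one row per scenario) and `trajectories`
#'   (tidy external concentrations with a `scenario` column).
#' @export
compare_geometries <- function(base_params,
                               modes = c("equal_volume", "equal_area"),
                               growth, mt_diameter_nm = 50,
                               onset_threshold_mM = 1, ...) {
  stopifnot(inherits(base_params, "pdu_params"))
  if (length(modes) > 0) {
    modes <- match.arg(modes, c("equal_volume", "equal_area"),
                       several.ok = TRUE)
  }
  cyl <- make_cylinder(mt_diameter_nm,
                       base_params$cell$cell_length_um * NM_PER_UM)
  scen <- list(base = base_params)
  for (m in modes) {
    p <- base_params
    p$compartments <- match_ensemble(base_params$compartments, cyl, m)
    scen[[m]] <- p
  }
  sims <- lapply(scen, run_simulation, growth = growth, ...)
  summary <- do.call(rbind, lapply(names(sims), function(nmi) {
    s <- sims[[nmi]]
    pdo <- concentration_series(s, "external", "PDO")
    pald <- concentration_series(s, "external", "PALD")
    data.frame(
      scenario = nmi,
      compartment_count = s$params$compartments$count,
      total_area_um2 = s$params$compartments$total_area_um2,
      total_volume_um3 = s$params$compartments$total_volume_um3,
      lumen_vmax_scale = lumen_vmax_scale(s$params),
      pdo_depletion_h = depletion_time(pdo$time_h, pdo$concentration_mM),
      prop_onset_h = onset_time_of(s, "PROP", onset_threshold_mM),
      poh_onset_h = onset_time_of(s, "POH", onset_threshold_mM),
      peak_external_pald_mM = peak(pald$time_h, pald$concentration_mM)["c_peak"],
      peak_cytosol_pald_mM = {
        cs <- concentration_series(s, "cytosol", "PALD")
        peak(cs$time_h, cs$concentration_mM)["c_peak"]
      },
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  trajectories <- do.call(rbind, lapply(names(sims), function(nmi) {
    d <- as.data.frame(sims[[nmi]])
    d <- d[d$region == "external", ]
    d$scenario <- nmi
    d
  }))
  rownames(trajectories) <- NULL
  list(summary = summary, trajectories = trajectories, sims = sims)
}

onset_time_of <- function(sim, species, threshold) {
  s <- concentration_series(sim, "external", species)
  onset_time(s$time_h, s$concentration_mM, threshold)
}
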