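#' Normalized local sensitivity analysis
#'
#' Normalized sensitivities S = (p/Q)(dQ/dp) — the log-log slope of a
#' quantity of interest with respect to a parameter — computed by central
#' finite differences on multiplicative perturbations:
#' S = [Q(p(1+e)) - Q(p(1-e))] / (2 e Q(p)).
#'
#' @name sensitivity
NULL

#' Built-in quantities of interest
#'
#' `peak_external_pald` (the default QoI: maximum external propionaldehyde
#' over the horizon), `peak_cytosol_pald`, `pdo_depletion_h`,
#' `prop_onset_h`.
#'
#' @param name QoI name.
#' @return A function of a `pdu_sim` returning a scalar.
#' @export
qoi_function <- function(name = c("peak_external_pald", "peak_cytosol_pald",
                                  "pdo_depletion_h", "prop_onset_h")) {
  name <- match.arg(name)
  switch(name,
    peak_external_pald = function(sim) {
      s <- concentration_series(sim, "external", "PALD")
      unname(peak(s$time_h, s$concentration_mM)["c_peak"])
    },
    peak_cytosol_pald = function(sim) {
      s <- concentration_series(sim, "cytosol", "PALD")
      unname(peak(s$time_h, s$concentration_mM)["c_peak"])
    },
    pdo_depletion_h = function(sim) {
      s <- concentration_series(sim, "external", "PDO")
      depletion_time(s$time_h, s$concentration_mM)
    },
    prop_onset_h = function(sim) onset_time_of(sim, "PROP", 1))
}

#' Normalized local sensitivity of one parameter
#'
#' @param params A `pdu_params`.
#' @param growth A `growth_curve`.
#' @param parameter Parameter name (see [perturbable_parameters()]).
#' @param qoi A function of a `pdu_sim` returning a scalar, or the name of a
#'   built-in QoI (default `"peak_external_pald"`).
#' @param rel_step Relative perturbation e (default 0.01).
#' @param ... Passed to [run_simulation()].
#' @return One-row data frame: `parameter`, `qoi`, `S` (dimensionless),
#'   `rel_step`, `method`, and the central value `Q0`.
#' @export
local_sensitivity <- function(params, growth, parameter,
                              qoi = "peak_external_pald", rel_step = 0.01,
                              ...) {
  stopifnot(inherits(params, "pdu_params"), rel_step > 0, rel_step < 1)
  qoi_name <- if (is.character(qoi)) qoi else "custom"
  f <- if (is.character(qoi)) qoi_function(qoi) else match.fun(qoi)
  Qof <- function(p) f(run_simulation(p, growth, ...))
  Q0 <- Qof(params)
  if (!is.finite(Q0) || Q0 == 0) {
    warning("QoI is zero or undefined at the base point; S undefined")
    S <- NA_real_
  } else {
    Qp <- Qof(scale_param(params, parameter, 1 + rel_step))
    Qm <- Qof(scale_param(params, parameter, 1 - rel_step))
    S <- (Qp - Qm) / (2 * rel_step * Q0)
  }
  data.frame(parameter = parameter, qoi = qoi_name, S = S,
             rel_step = rel_step, method = "central", Q0 = Q0,
             stringsAsFactors = FALSE)
}

#' Sensitivity sweep with |S| ranking
#'
#' @param params A `pdu_params`.
#' @param growth A `growth_curve`.
#' @param parameters `"all"` (every perturbable scalar),
#'   `"morphological"` (the aggregate geometric features, see
#'   [morphological_parameters()]), or an explicit character vector
#'   (duplicates are an error).
#' @param qoi As in [local_sensitivity()].
#' @param rel_step Relative step (default 0.01).
#' @param ... Passed to [run_simulation()].
#' @return Data frame of sensitivities sorted by decreasing |S|.
#' @export
sensitivity_sweep <- function(params, growth, parameters = "all",
                              qoi = "peak_external_pald", rel_step = 0.01,
                              ...) {
  if (identical(parameters, "all")) {
    parameters <- perturbable_parameters()
  } else if (identical(parameters, "morphological")) {
    parameters <- morphological_parameters()
  }
  if (anyDuplicated(parameters)) {
    stop("duplicate parameter names in sweep", call. = FALSE)
  }
  rows <- lapply(parameters, function(pn) {
    local_sensitivity(params, growth, pn, qoi = qoi, rel_step = rel_step, ...)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$S)), , drop = FALSE]
}
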