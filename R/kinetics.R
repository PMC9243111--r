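#' Rate laws and the three-region right-hand side
#'
#' State layout: 15 concentrations (mM), region-major —
#' lumen (PDO, PALD, PCOA, POH, PROP), then cytosol, then external.
#' The well-mixed ("broken compartment") limit drops the lumen block.
#'
#' @name kinetics
NULL

#' Michaelis-Menten rate
#'
#' `vmax * S / (km + S)`. Negative substrate values (solver transients) are
#' clamped to zero with a warning.
#'
#' @param substrate Substrate concentration, mM.
#' @param vmax Maximal rate, mM/h.
#' @param km Michaelis constant, mM (> 0).
#' @return Rate in mM/h; nondecreasing in `substrate`, bounded by `vmax`.
#' @export
mm_rate <- function(substrate, vmax, km) {
  stopifnot(is.numeric(substrate), is.numeric(vmax), is.numeric(km))
  if (any(km <= 0)) stop("km must be positive", call. = FALSE)
  if (any(substrate < 0)) {
    warning("negative substrate concentration clamped to 0")
    substrate <- pmax(substrate, 0)
  }
  vmax * substrate / (km + substrate)
}

#' Net rate of a reversible Michaelis-Menten step
#'
#' Independent forward and reverse saturating terms; positive values indicate
#' net forward flux. With `vmax_rev = 0` this reduces exactly to [mm_rate()].
#'
#' @param fwd_substrate Forward substrate concentration, mM.
#' @param rev_substrate Reverse substrate (product) concentration, mM.
#' @param kin An `enzyme_kinetics` object.
#' @return Net rate, mM/h.
#' @export
net_reversible_rate <- function(fwd_substrate, rev_substrate, kin) {
  stopifnot(inherits(kin, "enzyme_kinetics"))
  fwd <- mm_rate(fwd_substrate, kin$vmax_fwd, kin$km_fwd)
  if (kin$vmax_rev > 0) {
    fwd - mm_rate(rev_substrate, kin$vmax_rev, kin$km_rev)
  } else {
    fwd
  }
}

#' Passive transport flux across a barrier
#'
#' `permeability * area * (c_out - c_in)`, in mM um^3 / h (amount per hour in
#' concentration-volume units). Antisymmetric under swapping the two
#' concentrations.
#'
#' @param permeability Permeability, um/h (>= 0).
#' @param area Barrier area, um^2 (>= 0).
#' @param c_out,c_in Concentrations on either side, mM.
#' @return Flux into the `c_in` side, mM um^3 / h.
#' @export
transport_flux <- function(permeability, area, c_out, c_in) {
  stopifnot(permeability >= 0, area >= 0)
  permeability * area * (c_out - c_in)
}

## Shared scalar pre-computation for both the R and compiled right-hand
## sides. Returns the constants of the ODE system in fixed order.
rhs_constants <- function(params) {
  g <- params$compartments$geometry
  end_area <- if (g$shape == "cylinder") g$end_area_um2 else 0
  kA_comp <- params$k_c_um_h *
    (g$lateral_area_um2 + params$end_permeability_multiplier * end_area)
  es <- lumen_vmax_scale(params)
  e <- params$enzymes
  list(
    kA_comp = kA_comp,
    V_comp = g$volume_per_compartment_um3,
    count = params$compartments$count,
    V_cyt = cytosol_volume(params),
    kmA_cell = params$k_m_um_h * params$cell$membrane_area_um2,
    mem = as.numeric(params$membrane_permeable),
    es = es,
    vC = e$PduCDE$vmax_fwd * es, kmC = e$PduCDE$km_fwd,
    vP = e$PduP$vmax_fwd * es, kmP = e$PduP$km_fwd,
    vPr = e$PduP$vmax_rev * es, kmPr = e$PduP$km_rev,
    vQ = e$PduQ$vmax_fwd * es, kmQ = e$PduQ$km_fwd,
    vQr = e$PduQ$vmax_rev * es, kmQr = e$PduQ$km_rev,
    vL = e$PduLW$vmax_fwd, kmL = e$PduLW$km_fwd
  )
}

mm0 <- function(S, v, k) v * pmax(S, 0) / (k + pmax(S, 0))

#' Right-hand side of the three-region ODE system
#'
#' Reference implementation in R (the compiled equivalent drives
#' [run_simulation()]). Per cell: the lumen exchanges with the cytosol across
#' the shell, the cytosol with the external medium across the membrane, and
#' the external medium is depleted in proportion to the instantaneous cell
#' density. PduCDE, PduP and PduQ act in the lumen; the lumped PduL/PduW step
#' acts in the cytosol. 1-propanol and propionate have no downstream sinks.
#'
#' Intracellular species are additionally diluted by growth at the specific
#' rate d log(n)/dt when `dilute_by_growth` is `TRUE` (the default), which
#' makes the volume- and cell-number-weighted species totals exactly
#' conservative for any growth curve; the term vanishes at constant density.
#'
#' @param t Time, h.
#' @param state Numeric vector of 15 concentrations (lumen, cytosol,
#'   external; species order PDO, PALD, PCOA, POH, PROP).
#' @param params A `pdu_params`.
#' @param growth A `growth_curve`.
#' @param dilute_by_growth Apply the intracellular growth-dilution term.
#' @return List with the 15 derivatives (deSolve convention).
#' @export
pdu_rhs <- function(t, state, params, growth, dilute_by_growth = TRUE) {
  k <- rhs_constants(params)
  lum <- state[1:5]; cyt <- state[6:10]; ext <- state[11:15]
  rho <- growth_density(growth, t) / 1e12  # cells per um^3
  mu <- if (dilute_by_growth) growth_log_slope(growth, t) else 0
  Tl <- (k$kA_comp / k$V_comp) * (cyt - lum)
  Tc <- (k$kA_comp * k$count / k$V_cyt) * (lum - cyt)
  Tm <- (k$kmA_cell / k$V_cyt) * k$mem * (ext - cyt)
  Te <- -rho * k$kmA_cell * k$mem * (ext - cyt)
  R_CDE <- mm0(lum[1], k$vC, k$kmC)
  R_P <- mm0(lum[2], k$vP, k$kmP) - mm0(lum[3], k$vPr, k$kmPr)
  R_Q <- mm0(lum[2], k$vQ, k$kmQ) - mm0(lum[4], k$vQr, k$kmQr)
  R_LW <- mm0(cyt[3], k$vL, k$kmL)
  list(c(Tl + c(-R_CDE, R_CDE - R_P - R_Q, R_P, R_Q, 0) - mu * lum,
         Tc + Tm + c(0, 0, -R_LW, 0, R_LW) - mu * cyt,
         Te))
}

#' Instantaneous specific growth rate of a growth curve
#'
#' Slope of log density at `t` under the piecewise log-linear interpolation
#' contract (zero beyond the sampled range).
#'
#' @param growth A `growth_curve`.
#' @param t Time, h.
#' @return Growth rate, 1/h.
#' @export
growth_log_slope <- function(growth, t) {
  h <- 1e-4
  (log(growth_density(growth, t + h)) -
     log(growth_density(growth, t - h))) / (2 * h)
}

#' Right-hand side of the well-mixed (broken compartment) limit
#'
#' The lumen region is absent and the formerly encapsulated enzymes act in
#' the cytosol. Under `fixed_total_enzyme` their maximal rates are rescaled
#' by total compartment volume / cytosol volume, so the enzyme amount per
#' cell matches the compartmentalized model. This is the k_c -> Inf limit
#' and the model analogue of a strain whose shells cannot close.
#'
#' @param t Time, h.
#' @param state Numeric vector of 10 concentrations (cytosol, external).
#' @param params A `pdu_params`.
#' @param growth A `growth_curve`.
#' @param dilute_by_growth Apply the intracellular growth-dilution term.
#' @return List with the 10 derivatives.
#' @export
wellmixed_rhs <- function(t, state, params, growth, dilute_by_growth = TRUE) {
  k <- rhs_constants(params)
  cyt <- state[1:5]; ext <- state[6:10]
  rho <- growth_density(growth, t) / 1e12
  mu <- if (dilute_by_growth) growth_log_slope(growth, t) else 0
  f <- k$V_comp * k$count / k$V_cyt  # dilute lumen enzymes into the cytosol
  Tm <- (k$kmA_cell / k$V_cyt) * k$mem * (ext - cyt)
  Te <- -rho * k$kmA_cell * k$mem * (ext - cyt)
  R_CDE <- mm0(cyt[1], k$vC * f, k$kmC)
  R_P <- mm0(cyt[2], k$vP * f, k$kmP) - mm0(cyt[3], k$vPr * f, k$kmPr)
  R_Q <- mm0(cyt[2], k$vQ * f, k$kmQ) - mm0(cyt[4], k$vQr * f, k$kmQr)
  R_LW <- mm0(cyt[3], k$vL, k$kmL)
  list(c(Tm + c(-R_CDE, R_CDE - R_P - R_Q, R_P - R_LW, R_Q, R_LW) - mu * cyt,
         Te))
}
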