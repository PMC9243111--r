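# Shared fixtures. Everything is generated in code; simulations for the
# slower checks are cached per test run.

default_growth <- function() generate_growth_curve(growth_model())

flat_growth <- function(density = 5e8) {
  growth_curve(c(0, 30), c(density, density))
}

# parameters with all enzymatic activity off (transport-only system)
transport_only_params <- function(k_c = 5000, k_m = 3600) {
  enz <- list(
    PduCDE = enzyme_kinetics("PduCDE", vmax_fwd = 0, km_fwd = 0.5),
    PduP = enzyme_kinetics("PduP", vmax_fwd = 0, km_fwd = 25),
    PduQ = enzyme_kinetics("PduQ", vmax_fwd = 0, km_fwd = 25),
    PduLW = enzyme_kinetics("PduLW", vmax_fwd = 0, km_fwd = 0.5))
  pdu_model_parameters(enzymes = enz, k_c_um_h = k_c, k_m_um_h = k_m,
                       membrane_permeable = c(PDO = TRUE, PALD = TRUE,
                                              PCOA = TRUE, POH = TRUE,
                                              PROP = TRUE))
}

base_sim_cache <- new.env(parent = emptyenv())

cached_base_sim <- function() {
  if (is.null(base_sim_cache$sim)) {
    base_sim_cache$sim <- run_simulation(pdu_model_parameters(),
                                         default_growth())
  }
  base_sim_cache$sim
}

cached_calibration <- function() {
  if (is.null(base_sim_cache$cal)) {
    base_sim_cache$cal <- calibrate(pdu_model_parameters(),
                                    calibration_targets(), default_growth())
  }
  base_sim_cache$cal
}

# per-species relative deviation between two external trajectories
external_rel_dev <- function(sim_a, sim_b) {
  vapply(SPECIES <- c("PDO", "PALD", "PCOA", "POH", "PROP"), function(s) {
    a <- concentration_series(sim_a, "external", s)$concentration_mM
    b <- concentration_series(sim_b, "external", s)$concentration_mM
    max(abs(a - b)) / max(max(abs(b)), 1e-9)
  }, numeric(1))
}
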