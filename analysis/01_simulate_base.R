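#!/usr/bin/env Rscript
# Base case: 15 spherical microcompartments (140 nm) per cell, 55 mM external
# 1,2-propanediol, synthetic wild-type growth curve. Integrates the
# three-region model over 30 h and summarizes the external metabolite
# dynamics that an HPLC time course would see.

suppressPackageStartupMessages(library(pdukinetics))
dir.create("results", showWarnings = FALSE)

params <- pdu_model_parameters()
growth <- generate_growth_curve(growth_model())
sim <- run_simulation(params, growth)

write_timeseries(sim, "results/base_trajectories.csv")
write_timeseries(data.frame(time_h = growth$times_h,
                            density_cells_ml = growth$density_cells_ml),
                 "results/growth_curve.csv")

pdo <- concentration_series(sim, "external", "PDO")
pald_ext <- concentration_series(sim, "external", "PALD")
pald_cyt <- concentration_series(sim, "cytosol", "PALD")
prop <- concentration_series(sim, "external", "PROP")
poh <- concentration_series(sim, "external", "POH")

summary <- data.frame(
  quantity = c("pdo_depletion_h", "prop_onset_h", "poh_onset_h",
               "peak_external_pald_mM", "peak_cytosol_pald_mM",
               "peak_external_pald_time_h", "doubling_time_3_9_h",
               "doubling_time_12_18_h", "conservation_residual"),
  value = c(depletion_time(pdo$time_h, pdo$concentration_mM),
            onset_time(prop$time_h, prop$concentration_mM, 1),
            onset_time(poh$time_h, poh$concentration_mM, 1),
            peak(pald_ext$time_h, pald_ext$concentration_mM)["c_peak"],
            peak(pald_cyt$time_h, pald_cyt$concentration_mM)["c_peak"],
            peak(pald_ext$time_h, pald_ext$concentration_mM)["t_peak"],
            doubling_time(growth, c(3, 9)),
            doubling_time(growth, c(12, 18)),
            sim$diagnostics$conservation_residual))
write.csv(summary, "results/base_summary.csv", row.names = FALSE)

cat("Base spherical-MCP case (calibrated defaults):\n")
cat(sprintf("  1,2-propanediol depleted (<1%% of 55 mM) at %.2f h\n",
            summary$value[1]))
cat(sprintf("  propionate onset (1 mM) at %.2f h; 1-propanol at %.2f h\n",
            summary$value[2], summary$value[3]))
cat(sprintf("  propionaldehyde peak: %.1f mM external / %.1f mM cytosolic at %.1f h\n",
            summary$value[4], summary$value[5], summary$value[6]))
cat(sprintf("  growth-curve doubling times: %.2f h (3-9 h), %.2f h (12-18 h)\n",
            summary$value[7], summary$value[8]))
cat(sprintf("  carbon-conservation residual: %.2e\n", summary$value[9]))
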