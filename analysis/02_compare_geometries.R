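#!/usr/bin/env Rscript
# Microcompartments versus microtubes. Cylindrical microtubes (50 nm
# diameter, cell length) cannot match the spherical base case in both total
# volume and total surface area; the two limiting matches bracket the
# geometry effect. Equal volume exposes 1.9x the shell area and raises the
# aldehyde peak; equal area concentrates the same enzymes 1.9x into less
# volume and changes external profiles very little. An open-ended microtube
# variant (end caps at full shell permeability) is included for reference.

suppressPackageStartupMessages(library(pdukinetics))
dir.create("results", showWarnings = FALSE)

params <- pdu_model_parameters()
growth <- generate_growth_curve(growth_model())

base_ens <- params$compartments
cyl <- make_cylinder(50, params$cell$cell_length_um * 1000)
fold <- sa_v_fold_factor(70, 25)
cat(sprintf("Surface-area / enzyme-concentration fold factor: %.4f (reported as %.1f)\n",
            fold, signif(fold, 2)))
cat(sprintf("  equal-volume match: %.3f cylinders/cell;  equal-area: %.3f\n",
            match_ensemble(base_ens, cyl, "equal_volume")$count,
            match_ensemble(base_ens, cyl, "equal_area")$count))

cmp <- compare_geometries(params, growth = growth)

# open-ended equal-volume microtubes: end caps transport at k_c
open_p <- params
open_p$compartments <- match_ensemble(base_ens, cyl, "equal_volume")
open_p$end_permeability_multiplier <- 1
open_sim <- run_simulation(open_p, growth)
pald <- concentration_series(open_sim, "external", "PALD")
open_row <- cmp$summary[cmp$summary$scenario == "equal_volume", ]
open_row$scenario <- "equal_volume_open_ends"
open_row$peak_external_pald_mM <- peak(pald$time_h, pald$concentration_mM)["c_peak"]
pdo <- concentration_series(open_sim, "external", "PDO")
open_row$pdo_depletion_h <- depletion_time(pdo$time_h, pdo$concentration_mM)
summary <- rbind(cmp$summary, open_row)

write.csv(summary, "results/geometry_comparison.csv", row.names = FALSE)
write_timeseries(cmp$trajectories, "results/geometry_trajectories.csv")

cat("\nScenario summaries (external metabolites):\n")
print(summary[, c("scenario", "compartment_count", "peak_external_pald_mM",
                  "pdo_depletion_h", "prop_onset_h")], row.names = FALSE)
ev <- summary[summary$scenario == "equal_volume", "peak_external_pald_mM"]
bs <- summary[summary$scenario == "base", "peak_external_pald_mM"]
cat(sprintf("\nEqual-volume microtubes raise the external aldehyde peak by %.1f%%;\n",
            100 * (ev / bs - 1)))
cat("equal-area microtubes are nearly indistinguishable from the base case.\n")
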