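# pdukinetics

Systems-level kinetic model of the encapsulated 1,2-propanediol utilization
(Pdu) pathway, built to ask how the *shape* of a bacterial microcompartment
changes pathway behavior. In *Salmonella*, the Pdu pathway runs inside
~140 nm polyhedral protein shells (microcompartments, MCPs); when the vertex
protein cannot incorporate, the same shell proteins instead form long
~50 nm cylinders (microtubes, MTs). Because a sphere and a cylinder cannot
match in both surface area and volume, this geometry change necessarily
alters the surface-area-to-volume ratio of the encapsulated reaction
compartment — and with it the retention of the toxic propionaldehyde
intermediate.

The package is aimed at people modeling encapsulated metabolism: it provides
the geometry layer, the three-region ODE system, the calibration and
sensitivity machinery, and a synthetic-data generator for recovery studies,
plus a set of narrative analysis scripts (`analysis/01_...` to `05_...`)
that walk through the full study.

## Model

Five metabolites — 1,2-propanediol (PDO), propionaldehyde (PALD),
propionyl-CoA (PCOA), 1-propanol (POH), propionate (PROP) — in three
well-mixed regions: compartment lumen, cytosol, external medium. Per cell,
with Michaelis–Menten kinetics and passive transport,

* lumen: `dc/dt = (k_c A_comp / V_comp)(c_cyt − c_lum) + R_CDE, R_P, R_Q`
  (PduCDE: PDO→PALD, irreversible; PduP: PALD⇌PCOA; PduQ: PALD⇌POH)
* cytosol: shell exchange (×N compartments) + membrane exchange
  `(k_m A_cell / V_cyt)(c_ext − c_cyt)` + the lumped irreversible
  PduL/PduW step PCOA→PROP
* external: depleted in proportion to the instantaneous cell density n(t)
  taken from a growth curve (piecewise log-linear interpolation)

Shell permeability `k_c` is identical for all species; propionyl-CoA does
not cross the cell membrane. Intracellular species are diluted by growth at
rate `d ln n/dt`, which makes the culture-wide carbon balance exact. Units:
mM, h, µm. A cylinder exchanges through its lateral surface only (closed
ends by default; an end-permeability multiplier opens them).

The two microtube limiting cases follow from `match_ensemble()`: matched by
total volume, cylinders expose `2 r_s / (3 r_c)` = 1.87 ≈ 1.9× the shell
area; matched by total area they concentrate the same enzymes 1.9× into
less volume.

## Worked example

```r
library(pdukinetics)

params <- pdu_model_parameters()                  # calibrated base case
growth <- generate_growth_curve(growth_model())   # synthetic WT growth
sim    <- run_simulation(params, growth)          # 0-30 h, 0.1 h grid

pdo  <- concentration_series(sim, "external", "PDO")
pald <- concentration_series(sim, "external", "PALD")
depletion_time(pdo$time_h, pdo$concentration_mM)
peak(pald$time_h, pald$concentration_mM)
```

Running `Rscript analysis/01_simulate_base.R` prints:

```
Base spherical-MCP case (calibrated defaults):
  1,2-propanediol depleted (<1% of 55 mM) at 18.36 h
  propionate onset (1 mM) at 9.19 h; 1-propanol at 9.79 h
  propionaldehyde peak: 14.1 mM external / 14.1 mM cytosolic at 17.2 h
  growth-curve doubling times: 3.17 h (3-9 h), 9.20 h (12-18 h)
  carbon-conservation residual: 2.01e-04
```

That is the calibrated phenotype: the 55 mM substrate is consumed inside
the 10–20 h experimental window, the downstream products appear at ~10 h,
and the toxic aldehyde transient stays under the 16 mM growth-defect
ceiling. `analysis/02_compare_geometries.R` then shows the geometry effect
— equal-volume microtubes (4.39 cylinders/cell, 1.9× area) raise the
external aldehyde peak (14.30 vs 14.08 mM), while equal-area microtubes
(2.35 cylinders/cell, 1.9× enzyme concentration) reproduce the base
profiles to within a fraction of a percent — and
`analysis/04_sensitivity.R` confirms that among morphological features,
total compartment surface area has the largest normalized sensitivity of
peak external propionaldehyde.

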