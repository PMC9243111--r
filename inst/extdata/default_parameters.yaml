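# Default model parameters: symbol, value, unit, provenance, description.
# Provenance classes:
#   printed      — model dimension stated in the source study
#   literature   — magnitude informed by published enzyme/transport data
#   calibrated   — set by the calibration procedure (timescale + peak criteria)
#   design       — package design default (documented in the methods vignette)
- symbol: mcp_diameter_nm
  value: 140
  unit: nm
  provenance: printed
  description: Diameter of a spherical microcompartment.
- symbol: mcp_count
  value: 15
  unit: compartments/cell
  provenance: printed
  description: Microcompartments per cell in the base case.
- symbol: mt_diameter_nm
  value: 50
  unit: nm
  provenance: printed
  description: Diameter of a cylindrical microtube.
- symbol: cell_length_um
  value: 2.5
  unit: um
  provenance: printed
  description: Cell (and microtube) length.
- symbol: capsule_radius_um
  value: 0.5
  unit: um
  provenance: design
  description: Capsule-shaped cell radius (typical rod half-width).
- symbol: initial_external_PDO_mM
  value: 55
  unit: mM
  provenance: printed
  description: Initial external 1,2-propanediol concentration.
- symbol: k_c_um_h
  value: 5000
  unit: um/h
  provenance: calibrated
  description: Shell permeability, identical for all species.
- symbol: end_permeability_multiplier
  value: 0
  unit: dimensionless
  provenance: design
  description: Scale on shell permeability at cylinder end caps (0 = closed).
- symbol: k_m_um_h
  value: 3600
  unit: um/h
  provenance: literature
  description: Cell-membrane permeability (~1e-4 cm/s for small polar solutes).
- symbol: vmax_CDE
  value: 4.0e5
  unit: mM/h (lumen volume)
  provenance: literature
  description: PduCDE maximal rate (diol dehydratase turnover at lumen-scale enzyme concentration).
- symbol: km_CDE
  value: 0.5
  unit: mM
  provenance: literature
  description: PduCDE Michaelis constant for 1,2-propanediol.
- symbol: vmax_P
  value: 8.0e5
  unit: mM/h (lumen volume)
  provenance: calibrated
  description: PduP forward maximal rate (propionaldehyde -> propionyl-CoA).
- symbol: km_P
  value: 25
  unit: mM
  provenance: design
  description: PduP effective forward Michaelis constant (lumped, absorbs cofactor limitation).
- symbol: vmax_rev_P
  value: 8.0e3
  unit: mM/h (lumen volume)
  provenance: design
  description: PduP reverse maximal rate.
- symbol: km_rev_P
  value: 50
  unit: mM
  provenance: design
  description: PduP reverse Michaelis constant.
- symbol: vmax_Q
  value: 2.0e5
  unit: mM/h (lumen volume)
  provenance: calibrated
  description: PduQ forward maximal rate (propionaldehyde -> 1-propanol).
- symbol: km_Q
  value: 25
  unit: mM
  provenance: design
  description: PduQ effective forward Michaelis constant.
- symbol: vmax_rev_Q
  value: 2.0e4
  unit: mM/h (lumen volume)
  provenance: design
  description: PduQ reverse maximal rate (1-propanol oxidation back to the aldehyde).
- symbol: km_rev_Q
  value: 50
  unit: mM
  provenance: design
  description: PduQ reverse Michaelis constant.
- symbol: vmax_LW
  value: 500
  unit: mM/h (cytosol volume)
  provenance: design
  description: Lumped PduL/PduW maximal rate (capacity-limited cytosolic step setting propionate onset).
- symbol: km_LW
  value: 0.5
  unit: mM
  provenance: design
  description: Lumped PduL/PduW Michaelis constant for propionyl-CoA.
- symbol: growth_n0_cells_ml
  value: 5.0e7
  unit: cells/mL
  provenance: design
  description: Inoculum density of the synthetic wild-type growth curve.
- symbol: growth_lag_h
  value: 1
  unit: h
  provenance: design
  description: Lag phase of the synthetic growth curve.
- symbol: growth_td_early_h
  value: 3.17
  unit: h
  provenance: printed
  description: Wild-type doubling time in the 3-9 h window.
- symbol: growth_t_switch_h
  value: 12
  unit: h
  provenance: design
  description: Switch time between the fast and slow growth phases.
- symbol: growth_td_late_h
  value: 9.2
  unit: h
  provenance: printed
  description: Wild-type doubling time in the 12-18 h window.
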