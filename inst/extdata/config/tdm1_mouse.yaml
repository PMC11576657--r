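# T-DM1 in the mouse: plasma PK + tumor disposition + TGI defaults.
# Values are literature-informed package defaults in explicit units;
# the methods vignette documents the choices.
molecule:
  name: T-DM1
  linker_type: non_cleavable
  dar: 3.5
  k_dec: {value: 0.15, unit: 1/day}
  k_on_ab: {value: 7.3e+5, unit: 1/M/s}       # trastuzumab-HER2 association
  k_off_ab: {value: 31.5, unit: 1/day}       # Kd ~ 0.5 nM
  k_cleave: {value: 0.0, unit: 1/day}
  k_in_pl: {value: 1.0, unit: 1/day}         # lysosome->cytosol / media->cell
  k_out_pl: {value: 0.14, unit: 1/day}       # slow efflux of lys-MCC-DM1
  k_on_pl: {value: 8.64, unit: 1/nM/day}     # DM1 catabolite - tubulin
  k_off_pl: {value: 8.64, unit: 1/day}       # Kd ~ 1 nM
  mw_adc: {value: 148000, unit: g/mol}
  mw_pl: {value: 738, unit: g/mol}
system:
  species: mouse
  k_endo_her2: {value: 6.0, unit: 1/day}
  k_endo_her2ab: {value: 6.0, unit: 1/day}
  k_rec_her2: {value: 10.0, unit: 1/day}     # high HER2 recycling fraction
  k_rec_her2ab: {value: 10.0, unit: 1/day}
  k_deg_her2: {value: 2.8, unit: 1/day}
  k_deg_her2ab: {value: 2.8, unit: 1/day}
  r_total_per_cell: 1.0e+6                    # HER2 3+ xenograft line
  target_conc: {value: 65, unit: nM}         # effective tubulin concentration
  k12: {value: 0.30, unit: 1/day}
  k21: {value: 0.45, unit: 1/day}
  k12_pl: {value: 15.0, unit: 1/day}
  k21_pl: {value: 21.0, unit: 1/day}
  k_elim_ab: {value: 0.059754067290, unit: 1/day}   # ln2 / 11.6 d
  k_elim_pl: {value: 4.753009238125, unit: 1/day}     # ln2 / 3.5 h (DM1)
  v_central: {value: 1.0, unit: mL}
  v_peripheral: {value: 2.6, unit: mL}
  v_tumor_init: {value: 200, unit: mm^3}
  k_shed: {value: 0.0, unit: 1/day}          # trastuzumab does not bind mouse Her2
  t_half_sher2: {value: 1, unit: day}
  t_half_sher2ab: {value: 1, unit: day}
  n_healthy_central: 0
  n_healthy_peripheral: 0
  r_healthy_per_cell: 0
  d_ab: {value: 0.022, unit: cm^2/day}
  p_ab: {value: 334, unit: um/day}
  d_pl: {value: 0.25, unit: cm^2/day}
  p_pl: {value: 5.0, unit: cm/day}
  r_cap: {value: 8, unit: um}
  r_krogh: {value: 75, unit: um}
  eps_ab: 0.24
  eps_pl: 0.44
  cell_density: {value: 5.0e+5, unit: "cells/mm^3"}
  v_cell: {value: 1.0, unit: pL}
  body_weight: {value: 0.02, unit: kg}
tgi:
  t_double: {value: 9, unit: day}
  k_lin: {value: 25, unit: "mm^3/day"}
  v_tumor_max: {value: 3000, unit: mm^3}
  psi: 20
  tau: {value: 3, unit: day}
  k_kill_max: {value: 0.2, unit: 1/day}
  kc50: {value: 4000, unit: nM}
regimen:
  dose_mg_per_kg: {value: 3, unit: mg/kg}
  interval: {value: 21, unit: day}
  n_doses: 1
  analyte: adc
  route: bolus
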