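# T-DM1 in HER2+ metastatic breast cancer patients: human physiological
# volumes, soluble HER2 shedding, healthy-cell receptor sinks, and clinical
# tumor growth parameters.  Drug-effect parameters carry over from the
# mouse TGI calibration.
extends: tdm1_mouse.yaml
system:
  species: human
  r_total_per_cell: 1.0e+6                    # HER2 3+ stratum default
  v_central: {value: 3.0, unit: L}
  v_peripheral: {value: 3.1, unit: L}
  v_tumor_init: {value: 1.13097e+5, unit: mm^3}   # 60 mm baseline diameter
  k_shed: {value: 0.1, unit: 1/day}
  t_half_sher2: {value: 0.3, unit: day}
  t_half_sher2ab: {value: 2, unit: day}
  n_healthy_central: 1.0e+9
  n_healthy_peripheral: 1.0e+10
  r_healthy_per_cell: 1.0e+4
  body_weight: {value: 70, unit: kg}
tgi:
  t_double: {value: 40, unit: day}
  k_lin: {value: 500, unit: "mm^3/day"}
  v_tumor_max: {value: 1.0e+6, unit: mm^3}
  psi: 20
  tau: {value: 3, unit: day}
  k_kill_max: {value: 0.04, unit: 1/day}
  kc50: {value: 10000, unit: nM}
regimen:
  dose_mg_per_kg: {value: 3.6, unit: mg/kg}
  interval: {value: 21, unit: day}
  n_doses: 20
  analyte: adc
  route: bolus
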