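# T-DXd in HER2+ patients: human system over the T-DXd molecule.
extends: tdm1_human.yaml
molecule:
  name: T-DXd
  linker_type: cleavable
  dar: 8
  k_dec: {value: 0.014, unit: 1/day}
  k_cleave: {value: 2.0, unit: 1/day}
  k_in_pl: {value: 12.0, unit: 1/day}
  k_out_pl: {value: 18.0, unit: 1/day}
  k_on_pl: {value: 0.864, unit: 1/nM/day}
  k_off_pl: {value: 43.2, unit: 1/day}
  mw_adc: {value: 154000, unit: g/mol}
  mw_pl: {value: 494, unit: g/mol}
system:
  target_conc: {value: 100, unit: nM}
  k_elim_pl: {value: 20.79441541680, unit: 1/day}
tgi:
  k_kill_max: {value: 0.04, unit: 1/day}
  kc50: {value: 250, unit: nM}
regimen:
  dose_mg_per_kg: {value: 5.4, unit: mg/kg}
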