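# T-DXd in the mouse.  Shares antibody distribution and half-life with
# T-DM1; deconjugation is much slower (more stable linker) and the payload
# is released by endo/lysosomal linker cleavage.
extends: tdm1_mouse.yaml
molecule:
  name: T-DXd
  linker_type: cleavable
  dar: 8
  k_dec: {value: 0.014, unit: 1/day}
  k_cleave: {value: 2.0, unit: 1/day}
  k_in_pl: {value: 12.0, unit: 1/day}        # membrane-permeable payload
  k_out_pl: {value: 18.0, unit: 1/day}
  k_on_pl: {value: 0.864, unit: 1/nM/day}    # DXd - TOPO-1
  k_off_pl: {value: 43.2, unit: 1/day}       # Kd ~ 50 nM
  mw_adc: {value: 154000, unit: g/mol}
  mw_pl: {value: 494, unit: g/mol}
system:
  target_conc: {value: 100, unit: nM}        # TOPO-1
  k_elim_pl: {value: 20.79441541680, unit: 1/day}   # ln2 / 0.8 h (DXd)
tgi:
  k_kill_max: {value: 0.25, unit: 1/day}
  kc50: {value: 150, unit: nM}
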