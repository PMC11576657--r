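# In vitro incubation of T-DM1 with a HER2 3+ breast cancer line.
extends: tdm1_mouse.yaml
invitro:
  n_cells: 1.0e+6
  v_media: {value: 1, unit: mL}
  dose_conc: {value: 10, unit: nM}
  duration: {value: 7, unit: day}
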