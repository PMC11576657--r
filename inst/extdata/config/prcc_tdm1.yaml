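# Global sensitivity (LHS-PRCC) study on the T-DM1 human model:
# n = 1000 samples, 3.6 mg/kg Q3W x 4, tumor volume AUC over 12 weeks.
# Ranges are ten-fold below/above the default value unless a tighter
# literature range applies.
extends: tdm1_human.yaml
regimen:
  dose_mg_per_kg: {value: 3.6, unit: mg/kg}
  interval: {value: 21, unit: day}
  n_doses: 4
prcc:
  n_samples: 1000
  output: tumor_volume_auc
  window: {value: 84, unit: day}
  parameters:
    - name: tgi.t_double
      lower: {value: 4, unit: day}
      upper: {value: 400, unit: day}
      dist: loguniform
    - name: tgi.k_lin
      lower: {value: 50, unit: "mm^3/day"}
      upper: {value: 5000, unit: "mm^3/day"}
      dist: loguniform
    - name: tgi.tau
      lower: {value: 0.3, unit: day}
      upper: {value: 30, unit: day}
      dist: loguniform
    - name: tgi.k_kill_max
      lower: {value: 0.1, unit: 1/day}
      upper: {value: 10, unit: 1/day}
      dist: loguniform
    - name: tgi.kc50
      lower: {value: 0.8, unit: nM}
      upper: {value: 80, unit: nM}
      dist: loguniform
    - name: molecule.dar
      lower: 1
      upper: 8
      dist: uniform
    - name: molecule.k_dec
      lower: {value: 0.015, unit: 1/day}
      upper: {value: 1.5, unit: 1/day}
      dist: loguniform
    - name: system.k_elim_ab
      lower: {value: 0.006, unit: 1/day}
      upper: {value: 0.6, unit: 1/day}
      dist: loguniform
    - name: system.p_ab
      lower: {value: 33.4, unit: um/day}
      upper: {value: 3340, unit: um/day}
      dist: loguniform
    - name: system.t_half_sher2
      lower: {value: 0.03, unit: day}
      upper: {value: 3, unit: day}
      dist: loguniform
    - name: system.n_healthy_central
      lower: 1.0e+8
      upper: 1.0e+10
      dist: loguniform
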