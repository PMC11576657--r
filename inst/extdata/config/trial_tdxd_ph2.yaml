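# Virtual-trial emulation of a phase 2 study of T-DXd:
# 184 HER2+ patients, 5.4 mg/kg IV Q3W, 20 months.
extends: tdxd_human.yaml
trial:
  label: tdxd_phase2
  n_patients: 184
  duration: {value: 20, unit: months}
  assessment_interval: {value: 42, unit: day}
  dropout_rate: {value: 0.001, unit: 1/day}
  her2_receptors_per_cell: 1.0e+6
  her2_strata: [2.0e+4, 1.0e+6]
  cv:
    t_double: 0.3
    k_lin: 0.3
    k_kill_max: 0.3
    kc50: 2.0
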