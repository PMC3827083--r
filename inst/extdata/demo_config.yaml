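seed: 101
simulation:
  n_mirnas: 200
  n_per_group: 6
  noise_sd: 0.3
  planted_effects:
    - {mirna: sim-miR-0001, log2fc: 2.5}
    - {mirna: sim-miR-0002, log2fc: 2.0}
    - {mirna: sim-miR-0003, log2fc: 1.8, gender: M}
    - {mirna: sim-miR-0004, log2fc: 2.2, gender: M}
    - {mirna: sim-miR-0005, log2fc: 3.0, gender: F}
detection:
  threshold_quantile: 0.5
diffexp:
  p_max: 0.05
  min_abs_log2fc: 1.5
  min_mean_percentile: 50
cluster:
  linkage: average
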