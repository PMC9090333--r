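# Headline-condition demo: continuous 15 ug/mL drug exposure, deletion in
# about a quarter of illuminated lineages, restoration in 37.3% of deleted.
input: simulate
n_lineages: 300
seed: 1
condition:
  strain_mode: reporter_cat
  cp_conc: 15.0
  tc_hours: continuous
  duration_h: 72.0
  pre_hours: 16.0
generator:
  p_del: 0.245
  p_restore: 0.373
classify:
  min_divisions: 3
  rate_floor: 0.05
stats:
  n_resamples: 1000
  spearman_method: fisher
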