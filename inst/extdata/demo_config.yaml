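# Self-contained demonstration analysis on synthetic summary statistics.
# Paths are relative to this file's directory.
outcome: demo/outcome.tsv
seed: 2026
methods:
  - ivw
  - ivw_penalized_robust
  - mr_egger
  - simple_median
  - weighted_median
  - weighted_mbe
  - mr_presso
parameters:
  n_boot: 1000
  n_sim: 1000
  phi: 1.0
  outlier_threshold: 0.05
palindromic_policy: infer_by_eaf
eaf_threshold: 0.42
leave_one_out:
  - synthetic trait
traits:
  - name: synthetic trait
    exposure: demo/exposure.tsv
    exclusions: demo/exclusions.tsv
    exposure_scale: 1-SD
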