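# Replication configuration for the published six-trait glycemic analysis
# against Alzheimer's disease.
#
# The per-SNP instrument tables are distributed as journal supplementary
# material and are NOT shipped with this package: place the SNP-exposure
# tables (SD2 layout) and the SNP-outcome table (SD3 layout, IGAP stage 1)
# as the files named below, in this package's extdata/supplementary/
# directory, converted to tab-separated text with the standard columns
# rsid, effect_allele, other_allele, eaf, beta, se, pvalue.
#
# Exclusion lists hold the variants the phenome-wide look-up flagged as
# associated with other traits at genome-wide significance.
outcome: supplementary/sd3_alzheimers_igap.tsv
seed: 20201116
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
  n_sim: 5000
  phi: 1.0
  outlier_threshold: 0.05
palindromic_policy: infer_by_eaf
eaf_threshold: 0.42
leave_one_out:
  - fasting glucose
  - HOMA-B
traits:
  - name: type 2 diabetes
    exposure: supplementary/sd2_type2diabetes.tsv
    exclusions: supplementary/exclusions_type2diabetes.tsv
    exposure_scale: log-odds
  - name: fasting glucose
    exposure: supplementary/sd2_fastingglucose.tsv
    exclusions: supplementary/exclusions_fastingglucose.tsv
    exposure_scale: 1-SD
  - name: fasting insulin
    exposure: supplementary/sd2_fastinginsulin.tsv
    exposure_scale: 1-SD (natural-log transformed)
  - name: HbA1c
    exposure: supplementary/sd2_hba1c.tsv
    exclusions: supplementary/exclusions_hba1c.tsv
    exposure_scale: "%-units"
  - name: HOMA-B
    exposure: supplementary/sd2_homab.tsv
    exclusions: supplementary/exclusions_homab.tsv
    exposure_scale: 1-SD lower (natural-log transformed)
    sign_flip: true
  - name: HOMA-IR
    exposure: supplementary/sd2_homair.tsv
    exposure_scale: 1-SD (natural-log transformed)
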