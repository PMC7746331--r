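Package: SummaryMR
Title: Two-Sample Mendelian Randomization with GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization from published GWAS summary
    association statistics. Reads per-SNP exposure and outcome tables, applies
    pleiotropy exclusion lists, harmonizes effect alleles across studies
    (including palindromic-variant policies), and estimates the causal effect
    of an exposure on a binary outcome with seven estimators: inverse-variance
    weighted (fixed and multiplicative random effects), penalized robust IVW,
    MR-Egger regression with pleiotropy intercept, simple and weighted median,
    the weighted mode-based estimate, and MR-PRESSO outlier detection and
    correction. Includes Cochran's Q heterogeneity test, leave-one-out
    sensitivity analysis, per-variant effect tables for scatter and forest
    displays, a deterministic synthetic summary-statistics generator with
    configurable pleiotropy for validation, and a pipeline driver that runs
    many traits against one outcome from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
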