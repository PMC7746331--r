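---
title: "Two-sample Mendelian randomization with SummaryMR: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with SummaryMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SummaryMR)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of an exposure on an outcome from observational
data. A variant is a valid instrument under three assumptions: it is
associated with the exposure; it is independent of confounders of the
exposure–outcome relationship; and it affects the outcome only through the
exposure (no horizontal pleiotropy). In the two-sample setting the SNP–
exposure associations $(\hat\beta_{Xj}, \sigma_{Xj})$ and SNP–outcome
associations $(\hat\beta_{Yj}, \sigma_{Yj})$ for $J$ independent variants
come from two non-overlapping GWAS, and only summary statistics are needed.

For a valid instrument the expected outcome association is proportional to
the exposure association, $\beta_{Yj} = \theta\,\beta_{Xj}$, so each variant
supplies a ratio (Wald) estimate $\hat\theta_j = \hat\beta_{Yj} /
\hat\beta_{Xj}$ with first-order standard error $\sigma_{Yj} /
|\hat\beta_{Xj}|$. Treating the exposure coefficients as measured without
error (the NOME convention) is standard for instruments that reached
genome-wide significance in large consortia; `ratioEstimates(...,
secondOrder = TRUE)` propagates the exposure-side variance for users who
want the conservative alternative. With a binary outcome modelled by
logistic regression, $\theta$ is a log odds ratio per unit of exposure and
results are reported as $e^\theta$ with 95% confidence bounds.

## The estimators

All seven estimators consume the same harmonized object and differ in which
subset of instruments they allow to be invalid.

**IVW.** Weighted least squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
through the origin with weights $\hat\beta_{Xj}^2/\sigma_{Yj}^2$ —
equivalently the inverse-variance weighted mean of the ratio estimates.
Consistent only if *every* instrument is valid. The default reports the
multiplicative random-effects standard error, the fixed-effects value
inflated by $\max\{1, \sqrt{Q/(J-1)}\}$ with $Q$ Cochran's heterogeneity
statistic: under homogeneity the two coincide, and under heterogeneity the
random-effects version is the conservative convention. The point estimate
is identical under both models; `model = "fixed"` selects the
fixed-effects standard error.

**Penalized robust IVW.** Each weight is multiplied by $\min(1,
s\,q_j)$, where $q_j$ is the upper-tail $\chi^2_1$ probability of variant
$j$'s heterogeneity contribution at the plain IVW estimate and $s$ is
`penaltyScale` (default 20: variants with $q_j > 0.05$ keep their full
weight). The effect is re-estimated by Huber M-regression through the
origin (`robustTuning` 1.345, the classical 95%-efficiency constant), and
the standard error carries the same multiplicative inflation, now from the
robust residual scale. Down-weighting is therefore reserved for variants
whose ratio estimates are individually implausible under homogeneity.

**MR-Egger.** The same weighted regression with a free intercept. The slope
is consistent under directional pleiotropy provided instrument strength is
independent of the direct effects (InSIDE); the intercept estimates the
average direct effect per variant, and its test is the package's
directional-pleiotropy diagnostic. Because the intercept is not invariant
to allele coding, `mrEgger()` first orients every exposure coefficient
positive (`orientPositive()`), which leaves all ratio estimates unchanged.
Inference uses the $t$ distribution with $J-2$ degrees of freedom — with
the small instrument counts typical of glycemic traits the normal
approximation is too liberal.

**Simple and weighted median.** The (weighted) median of the ratio
estimates; the weighted version interpolates the sorted ratios against the
cumulative standardized weights $s_j = \sum_{k \le j} w_k - w_j/2$ at
$1/2$. Consistent while at least half the instruments (or half the total
weight) are valid. Standard errors come from a parametric bootstrap that
redraws both $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ around their observed
values with their standard errors; the seed is mandatory, so results are
reproducible.

**Weighted mode-based estimate (MBE).** The mode of the weighted kernel
density of the ratio estimates, with weights proportional to the inverse
squared ratio standard errors and the modified Silverman bandwidth $h =
\phi \times 0.9 \min(sd^*, mad^*) J^{-1/5}$ built from the weighted
standard deviation and scaled median absolute deviation. Consistent when
the largest group of instruments sharing one ratio is the valid group
(zero modal pleiotropy). `phi` trades bias for variance; 1 is the cited
default. The density is evaluated by `stats::density` (gaussian kernel,
FFT) on 512 points spanning the ratio range $\pm 3h$; ties in the maximum
resolve to the smallest grid point, making the estimate deterministic.

**MR-PRESSO.** For each variant the expected outcome coefficient is
$\hat\theta_{(-j)}\hat\beta_{Xj}$ from the leave-one-out IVW fit, and the
observed statistic is the sum of outcome-standardized squared residuals.
Its null distribution is simulated by redrawing coefficients around those
expectations and *recomputing the leave-one-out fits inside every
replicate*. The global test reads off the Monte-Carlo tail probability;
per-variant contributions are tested the same way, Bonferroni-adjusted
across $J$; flagged variants are removed and IVW re-run; the distortion
test compares the raw-vs-corrected shift with the shift from removing
random subsets of the same size.

A consequence worth knowing: the per-variant Monte-Carlo p-values have
resolution $1/(n_{\text{sim}}+1)$, so after Bonferroni adjustment *no*
variant can be flagged at level $\alpha$ unless $n_{\text{sim}} >
J/\alpha$. With 50 instruments at $\alpha = 0.05$ that means more than
1000 simulations; the validation suite uses 3000 in that setting. The
default `nSim = 1000` suits the instrument counts (2–43) of typical
single-trait analyses.

## Harmonization

Estimation is only meaningful once both studies express each variant's
effect for the same allele. `harmonize()` matches variants by identifier,
flips the outcome coefficient when the allele labels are swapped, and
recognizes strand-complemented labels (A/T, C/G swaps across strands).
Palindromic variants — A/T or C/G pairs, identical to their own strand
complement — cannot be oriented from labels. The default policy
(`infer_by_eaf`) orients them by allele frequency and drops those whose
frequency falls in the ambiguous window 0.42–0.58 on either side, the
standard practice for summary-level MR; `drop` and `keep` are available
and every decision is written to the harmonization report, one row per
input variant. Variants absent from the outcome study are dropped and
reported, not proxied: proxy substitution requires an LD reference panel,
which is out of scope. Likewise the package treats instrument independence
(pairwise $r^2 < 0.20$) and pleiotropy screening as upstream facts: the
screen arrives as an explicit exclusion list (`applyExclusions()`), never
as a live database query, so a run is reproducible from its input files
alone.

## The synthetic-data generator

`simulateSummaryData()` draws true exposure effects from a normal
distribution truncated at $|\beta_X| \ge 0.01$ (weak-instrument ratios
explode as $\beta_X \to 0$; published instruments are far from zero),
then observed coefficients around the truth with per-variant standard
errors, and true outcome effects $\theta\beta_{Xj} + \alpha_j$. Direct
effects $\alpha_j$ are zero for valid variants; an `invalidFraction` of
variants receives $\alpha_j$ with configurable mean (directional) or mean
zero (balanced), and `insideViolation` correlates $\alpha_j$ with
instrument strength to break InSIDE on demand.

The defaults describe a realistic consortium-scale study: 30 instruments,
exposure effects $N(0.05, 0.02^2)$ in trait units with standard errors
drawn from $U(0.002, 0.005)$ (quantitative GWAS of $\sim 10^5$
individuals), outcome log-OR standard errors from $U(0.02, 0.05)$
(case-control GWAS of tens of thousands), and a causal effect of 0.3.
What the generator deliberately does *not* emulate: linkage disequilibrium
between instruments, sample overlap between the two studies, winner's
curse in instrument selection, and non-normal estimate distributions.
Passing tests therefore demonstrate correctness of the estimators under
the two-sample summary-data model, not robustness to those additional
real-data complications.

All draws happen in one fixed, documented order under a single
`set.seed(config@seed)`, so a configuration is exactly reproducible;
changing $J$ changes the whole stream (a per-variant counter-based stream
was considered and set aside — base R exposes no counter-based generator,
and whole-vector draws keep the generator simple and fast).
`simulateStudyTables()` additionally writes the dataset as a pair of
summary-statistics files with randomized non-palindromic allele labels,
optionally scrambling outcome allele order (with beta negation and
frequency complementation) so that round-tripping through `harmonize()`
must reproduce the generated dataset bit for bit — an end-to-end check of
the harmonization logic.

## Numerical and design choices

- **Bootstrap standard errors** use the standard deviation of the
  bootstrap estimates (1000 replicates by default; `nBoot = 0` returns
  the point estimate alone with `NA` uncertainty, intended for large
  simulation studies). Because the bootstrap redraws around *observed*
  coefficients, its draws carry two layers of noise; for the mode-based
  estimate this makes confidence intervals conservative — its measured
  coverage in the validation suite sits at the top of, or above, the
  nominal band, consistent with the method's own literature. We keep the
  prescribed bootstrap rather than deconvolving it.
- **Cochran's Q** is always centred at the fixed-effects IVW estimate
  (the definitional choice), even though the headline IVW is
  random-effects; the per-variant Q contributions are the same quantities
  used by the penalization and by MR-PRESSO.
- **Degenerate inputs**: exact-fit data short-circuit the robust
  regression (residual scale 0 would otherwise destabilize the
  M-estimator); ratio sets that are constant up to rounding return the
  point mass directly instead of building a zero-bandwidth density; a
  zero exposure coefficient is an error naming the variant, never a
  silent division.
- **Two-sided p-values** come from the normal distribution for Wald-type
  statistics and from $t_{J-2}$ for both MR-Egger coefficients. The
  significance convention in reports is $p < 0.05$ with no correction
  across traits, matching common practice in the applied literature; when
  several exposures are screened this is a caveat, not a recommendation.
- **Pipeline determinism**: per-method seeds are derived arithmetically
  from the single configured seed, so `runAnalysis()` twice on one
  configuration yields identical tables. Relative paths inside a YAML
  configuration resolve against the configuration file's directory.
- **Method gating** mirrors the applied convention: estimators that need
  more than two variants (all but IVW) are skipped, with the reason
  recorded in the bundle, for traits with $J \le 2$; MR-PRESSO needs
  $J \ge 4$ so each leave-one-out fit keeps three instruments.
- **HOMA-β-style direction flips**: a per-trait `sign_flip` negates the
  exposure coefficients before analysis so that effects are reported per
  unit *lower* exposure (e.g. declining β-cell function as the risk
  factor); ratio magnitudes are unchanged.

## Validation scale

The test suite validates against independent oracles (weighted `lm()`
fits, definitional sums, dense-grid kernel search) at $10^{-10}$ relative
tolerance, and by simulation with known truth: 200 replicates at $J =
100$ for coverage, 200 replicates at $J = 50$ with 40% invalid
instruments for robustness ordering, 500 replicates for the calibration
of the pleiotropy-intercept and heterogeneity tests, and 100 replicates
with a planted 10-σ outlier for MR-PRESSO detection. The intercept-test
calibration check simulates balanced pleiotropy with direct-effect
standard deviation at the low end of the outcome standard errors — the
regime where the weighted regression's multiplicative variance model
approximately holds; with direct effects substantially larger than the
outcome standard errors the $1/\sigma_{Yj}^2$ weights are mis-specified
and the test is anti-conservative, a known property of the method rather
than of this implementation.

## Known limitations

No LD-aware instrument selection, proxy lookup, multivariable or
bidirectional MR, and no modelling of sample overlap or winner's curse.
The package analyzes the instruments it is given; the scientific burden
of instrument validity — relevance, independence, exclusion restriction —
remains with the input data.

## A short session

```{r example, eval = FALSE}
cfg <- system.file("extdata", "demo_config.yaml", package = "SummaryMR")
bundle <- runAnalysis(cfg)
bundle$traits[["synthetic trait"]]$results
renderOutputs(bundle, "mr_output", formats = "tsv")
```
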