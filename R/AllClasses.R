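#' @import methods
NULL

#' Harmonized two-sample summary dataset
#'
#' Container for the per-variant association summaries that every estimator in
#' the package consumes: for each of J independent instruments, the SNP
#' effect on the exposure and on the outcome, both expressed for the same
#' effect allele, with their standard errors.  Objects are normally produced
#' by [harmonize()] or [simulateSummaryData()] rather than constructed by
#' hand.
#'
#' Vectors are parallel: element j of every slot refers to the variant
#' `snpIds[j]`.  Validity requires equal lengths (J >= 1), strictly positive
#' finite standard errors, finite coefficients, and no duplicated variant
#' identifiers.
#'
#' @slot traitName single string naming the exposure trait.
#' @slot snpIds character vector of variant identifiers (e.g. rs numbers).
#' @slot betaExposure numeric, SNP-exposure coefficients (log-odds for binary
#'   exposures, SD or trait units for quantitative ones).
#' @slot seExposure numeric, standard errors of `betaExposure`, > 0.
#' @slot betaOutcome numeric, SNP-outcome coefficients on the log-odds scale.
#' @slot seOutcome numeric, standard errors of `betaOutcome`, > 0.
#' @slot exposureScale free-text descriptor of the exposure units
#'   (e.g. `"1-SD"`, `"log-odds"`, `"%-units"`).
#'
#' @seealso [harmonize()], [mrIVW()], [cochranQ()]
#' @export
setClass("MRData",
  slots = c(
    traitName     = "character",
    snpIds        = "character",
    betaExposure  = "numeric",
    seExposure    = "numeric",
    betaOutcome   = "numeric",
    seOutcome     = "numeric",
    exposureScale = "character"
  ),
  prototype = prototype(traitName = "exposure", exposureScale = "1-SD")
)

setValidity("MRData", function(object) {
  msg <- character()
  J <- length(object@snpIds)
  if (J < 1L) msg <- c(msg, "at least one variant is required")
  lens <- c(length(object@betaExposure), length(object@seExposure),
            length(object@betaOutcome), length(object@seOutcome))
  if (any(lens != J))
    msg <- c(msg, "beta/se vectors must all have the same length as snpIds")
  if (anyDuplicated(object@snpIds))
    msg <- c(msg, "duplicated variant identifiers")
  if (length(msg) == 0L) {
    if (!all(is.finite(object@betaExposure)) || !all(is.finite(object@betaOutcome)))
      msg <- c(msg, "non-finite coefficients")
    if (!all(is.finite(object@seExposure)) || any(object@seExposure <= 0))
      msg <- c(msg, "exposure standard errors must be finite and > 0")
    if (!all(is.finite(object@seOutcome)) || any(object@seOutcome <= 0))
      msg <- c(msg, "outcome standard errors must be finite and > 0")
  }
  if (length(object@traitName) != 1L) msg <- c(msg, "traitName must be length 1")
  if (length(object@exposureScale) != 1L) msg <- c(msg, "exposureScale must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct an MRData object
#'
#' @param snpIds character vector of variant identifiers.
#' @param betaExposure,seExposure,betaOutcome,seOutcome numeric vectors
#'   parallel to `snpIds`; standard errors must be > 0.
#' @param traitName exposure trait label.
#' @param exposureScale exposure unit descriptor carried through to reports.
#' @return An [MRData-class] object.
#' @examples
#' d <- MRData(paste0("rs", 1:3), c(0.1, 0.2, 0.3), c(0.01, 0.01, 0.02),
#'             c(0.03, 0.05, 0.10), c(0.02, 0.02, 0.03))
#' nSnps(d)
#' @export
MRData <- function(snpIds, betaExposure, seExposure, betaOutcome, seOutcome,
                   traitName = "exposure", exposureScale = "1-SD") {
  new("MRData",
      traitName = as.character(traitName),
      snpIds = as.character(snpIds),
      betaExposure = as.numeric(betaExposure),
      seExposure = as.numeric(seExposure),
      betaOutcome = as.numeric(betaOutcome),
      seOutcome = as.numeric(seOutcome),
      exposureScale = as.character(exposureScale))
}

#' Causal-effect estimate
#'
#' Result of one MR estimator: the causal effect `theta` on the beta scale
#' (log odds of the outcome per unit of exposure), its standard error, 95%
#' confidence bounds, two-sided p-value, and the number of instruments used.
#' The odds-ratio view is obtained with [oddsRatio()].
#'
#' Bootstrap-based estimators called with `nBoot = 0` return the point
#' estimate with `NA` standard error, confidence bounds, and p-value; this is
#' intended for large simulation studies where only point estimates matter.
#'
#' @slot method estimator name.
#' @slot theta causal effect on the beta (log-OR) scale.
#' @slot se standard error of `theta` (NA when not computed).
#' @slot ciLow,ciHigh 95% confidence bounds on the beta scale.
#' @slot pvalue two-sided p-value.
#' @slot nSnps number of instruments used.
#' @export
setClass("MREstimate",
  slots = c(method = "character", theta = "numeric", se = "numeric",
            ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
            nSnps = "integer"))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (!is.finite(object@theta)) msg <- c(msg, "theta must be finite")
  if (!is.na(object@se) && object@se <= 0) msg <- c(msg, "se must be > 0")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !(object@ciLow <= object@theta && object@theta <= object@ciHigh))
    msg <- c(msg, "confidence bounds must bracket theta")
  if (!is.na(object@pvalue) && (object@pvalue < 0 || object@pvalue > 1))
    msg <- c(msg, "pvalue must lie in [0, 1]")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MR-Egger regression estimate
#'
#' Extends [MREstimate-class]: the inherited slots describe the slope (the
#' pleiotropy-robust causal estimate); the additional slots describe the
#' regression intercept, the average directional pleiotropic effect per
#' variant on the log-odds scale.  Slope and intercept come from one weighted
#' regression fit.  An intercept that differs from zero signals directional
#' pleiotropy.
#'
#' @slot intercept intercept estimate (log-odds per variant).
#' @slot interceptSE its standard error.
#' @slot interceptCILow,interceptCIHigh 95% confidence bounds (t-based).
#' @slot interceptPValue two-sided p-value of the pleiotropy test.
#' @export
setClass("MREggerEstimate",
  contains = "MREstimate",
  slots = c(intercept = "numeric", interceptSE = "numeric",
            interceptCILow = "numeric", interceptCIHigh = "numeric",
            interceptPValue = "numeric"))

setClassUnion("MREstimateOrNULL", c("MREstimate", "NULL"))

#' MR-PRESSO result
#'
#' Output of [mrPresso()]: the global heterogeneity (residual sum of squares)
#' test, per-variant outlier tests, the outlier-corrected IVW estimate, and
#' the distortion test comparing raw and corrected estimates.
#'
#' @slot snpIds variant identifiers of the analyzed dataset.
#' @slot globalRSS observed standardized residual sum of squares.
#' @slot globalP Monte-Carlo tail probability of `globalRSS`.
#' @slot contributions per-variant observed RSS contributions.
#' @slot outlierPValues per-variant Monte-Carlo p-values, Bonferroni adjusted.
#' @slot outlierIndices indices of variants flagged at the threshold.
#' @slot raw IVW estimate on all variants.
#' @slot corrected IVW estimate after outlier removal (NULL if every variant
#'   was flagged).
#' @slot distortionP tail probability that the raw-vs-corrected difference is
#'   compatible with removing a random variant subset (NA when no outliers).
#' @slot nSim number of Monte-Carlo replicates.
#' @slot seed RNG seed used.
#' @slot allFlagged TRUE when every variant was flagged as an outlier.
#' @export
setClass("MRPressoResult",
  slots = c(snpIds = "character", globalRSS = "numeric", globalP = "numeric",
            contributions = "numeric", outlierPValues = "numeric",
            outlierIndices = "integer", raw = "MREstimate",
            corrected = "MREstimateOrNULL", distortionP = "numeric",
            nSim = "integer", seed = "integer", allFlagged = "logical"))

setValidity("MRPressoResult", function(object) {
  msg <- character()
  if (object@globalP < 0 || object@globalP > 1) msg <- c(msg, "globalP outside [0,1]")
  if (any(object@outlierPValues < 0 | object@outlierPValues > 1))
    msg <- c(msg, "outlier p-values outside [0,1]")
  J <- length(object@snpIds)
  if (length(object@outlierIndices) &&
      (min(object@outlierIndices) < 1L || max(object@outlierIndices) > J))
    msg <- c(msg, "outlier indices outside 1..J")
  if (!is.null(object@corrected) &&
      object@corrected@nSnps != J - length(object@outlierIndices))
    msg <- c(msg, "corrected estimate must use J - #outliers instruments")
  if (length(msg)) msg else TRUE
})

#' Cochran's Q heterogeneity result
#'
#' @slot q Cochran's Q statistic (weighted squared deviations of per-variant
#'   ratio estimates around the fixed-effects IVW estimate).
#' @slot df degrees of freedom, J - 1.
#' @slot pvalue upper tail of the chi-square distribution with `df` df.
#' @export
setClass("MRHeterogeneity",
  slots = c(q = "numeric", df = "integer", pvalue = "numeric"))

setValidity("MRHeterogeneity", function(object) {
  msg <- character()
  if (object@q < 0) msg <- c(msg, "q must be >= 0")
  if (object@df < 0L) msg <- c(msg, "df must be >= 0")
  if (object@pvalue <= 0 || object@pvalue > 1) msg <- c(msg, "pvalue outside (0,1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic two-sample study configuration
#'
#' Generative model for synthetic GWAS summary statistics: J instruments with
#' true exposure effects drawn from a truncated normal, observed exposure and
#' outcome coefficients drawn around their true values with per-variant
#' standard errors, a causal effect `thetaTrue`, and optional per-variant
#' direct (pleiotropic) effects on the outcome.
#'
#' The pleiotropy model: a fraction `invalidFraction` of variants receive a
#' direct effect alpha_j with mean `pleiotropyMean` (forced to 0 under
#' `"balanced"`) and sd `pleiotropySd`; `insideViolation` is the correlation
#' between alpha_j and the true exposure effect, 0 under the InSIDE
#' assumption.
#'
#' @slot nSnps number of instruments J.
#' @slot thetaTrue simulated causal effect (log-OR per exposure unit).
#' @slot exposureEffectMean,exposureEffectSd normal distribution of true
#'   SNP-exposure effects, truncated at absolute value >= 0.01.
#' @slot seExposureRange,seOutcomeRange uniform ranges for per-variant
#'   standard errors, (lo, hi) with 0 < lo <= hi.
#' @slot pleiotropyMode one of "none", "balanced", "directional".
#' @slot pleiotropySd sd of direct effects alpha_j.
#' @slot pleiotropyMean mean of alpha_j (ignored for "none", 0 for "balanced").
#' @slot invalidFraction share of variants receiving pleiotropy, in [0,1].
#' @slot insideViolation correlation of alpha_j with true exposure effects.
#' @slot seed integer RNG seed.
#' @seealso [simConfig()], [simulateSummaryData()]
#' @export
setClass("MRSimConfig",
  slots = c(nSnps = "integer", thetaTrue = "numeric",
            exposureEffectMean = "numeric", exposureEffectSd = "numeric",
            seExposureRange = "numeric", seOutcomeRange = "numeric",
            pleiotropyMode = "character", pleiotropySd = "numeric",
            pleiotropyMean = "numeric", invalidFraction = "numeric",
            insideViolation = "numeric", seed = "integer"))

setValidity("MRSimConfig", function(object) {
  msg <- character()
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (!is.finite(object@thetaTrue)) msg <- c(msg, "thetaTrue must be finite")
  if (object@exposureEffectSd < 0) msg <- c(msg, "exposureEffectSd must be >= 0")
  for (nm in c("seExposureRange", "seOutcomeRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
      msg <- c(msg, sprintf("%s must be positive and ordered (lo <= hi)", nm))
  }
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional"))
    msg <- c(msg, "pleiotropyMode must be none/balanced/directional")
  if (object@pleiotropySd < 0) msg <- c(msg, "pleiotropySd must be >= 0")
  if (object@invalidFraction < 0 || object@invalidFraction > 1)
    msg <- c(msg, "invalidFraction must lie in [0,1]")
  if (abs(object@insideViolation) > 1)
    msg <- c(msg, "insideViolation must lie in [-1,1]")
  if (is.na(object@seed)) msg <- c(msg, "seed is required")
  if (length(msg)) msg else TRUE
})
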