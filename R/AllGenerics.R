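# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' Number of instruments
#' @param x an object holding per-variant data or an estimate.
#' @return integer count of variants.
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' Variant identifiers
#' @param x an object holding per-variant data.
#' @return character vector of variant ids.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' Exposure trait label
#' @param x an [MRData-class] object.
#' @return single string.
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' Exposure unit descriptor
#' @param x an [MRData-class] object.
#' @return single string (e.g. "1-SD").
#' @export
setGeneric("exposureScale", function(x) standardGeneric("exposureScale"))

#' SNP-exposure coefficients
#' @param x an [MRData-class] object.
#' @return numeric vector.
#' @export
setGeneric("betaExposure", function(x) standardGeneric("betaExposure"))

#' Standard errors of the SNP-exposure coefficients
#' @param x an [MRData-class] object.
#' @return numeric vector.
#' @export
setGeneric("seExposure", function(x) standardGeneric("seExposure"))

#' SNP-outcome coefficients
#' @param x an [MRData-class] object.
#' @return numeric vector.
#' @export
setGeneric("betaOutcome", function(x) standardGeneric("betaOutcome"))

#' Standard errors of the SNP-outcome coefficients
#' @param x an [MRData-class] object.
#' @return numeric vector.
#' @export
setGeneric("seOutcome", function(x) standardGeneric("seOutcome"))

#' Causal-effect point estimate (log-OR scale)
#' @param x an [MREstimate-class] object.
#' @return numeric scalar.
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' Standard error of an estimate
#' @param x an [MREstimate-class] object.
#' @return numeric scalar (NA when not computed).
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' 95% confidence interval (log-OR scale)
#' @param x an [MREstimate-class] object.
#' @return numeric length-2 vector (low, high).
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' Two-sided p-value
#' @param x an estimate or test object.
#' @return numeric scalar.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Estimator name
#' @param x an [MREstimate-class] object.
#' @return single string.
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' Odds-ratio view of an estimate
#'
#' Exponentiates the causal estimate and its 95% confidence bounds, giving
#' the odds ratio of the outcome per unit of exposure.
#'
#' @param x an [MREstimate-class] object.
#' @return named numeric vector `c(OR=, OR_low=, OR_high=)`, all > 0.
#' @examples
#' est <- new("MREstimate", method = "IVW", theta = 0.2852, se = 0.1216,
#'            ciLow = 0.2852 - qnorm(0.975) * 0.1216,
#'            ciHigh = 0.2852 + qnorm(0.975) * 0.1216,
#'            pvalue = 0.019, nSnps = 28L)
#' round(oddsRatio(est), 2)   # 1.33 (1.05, 1.69)
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' MR-Egger intercept (directional-pleiotropy test)
#' @param x an [MREggerEstimate-class] object.
#' @return named list: estimate, se, ciLow, ciHigh, pvalue, and `odds`
#'   (the exponentiated intercept with its CI).
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))

#' Observed global RSS of the MR-PRESSO test
#' @param x an [MRPressoResult-class] object.
#' @return numeric scalar.
#' @export
setGeneric("globalRSS", function(x) standardGeneric("globalRSS"))

#' Global MR-PRESSO Monte-Carlo p-value
#' @param x an [MRPressoResult-class] object.
#' @return numeric scalar.
#' @export
setGeneric("globalPValue", function(x) standardGeneric("globalPValue"))

#' Indices of variants flagged as outliers
#' @param x an [MRPressoResult-class] object.
#' @return integer vector (possibly empty).
#' @export
setGeneric("outlierIndices", function(x) standardGeneric("outlierIndices"))

#' Outlier-corrected estimate
#' @param x an [MRPressoResult-class] object.
#' @return an [MREstimate-class], or NULL when every variant was flagged.
#' @export
setGeneric("correctedEstimate", function(x) standardGeneric("correctedEstimate"))

#' Distortion-test p-value
#' @param x an [MRPressoResult-class] object.
#' @return numeric scalar (NA when no outliers were flagged).
#' @export
setGeneric("distortionPValue", function(x) standardGeneric("distortionPValue"))

#' Per-variant MR-PRESSO outlier report
#' @param x an [MRPressoResult-class] object.
#' @return data.frame with columns rsid, contribution, p_adjusted, flagged.
#' @export
setGeneric("outlierTable", function(x) standardGeneric("outlierTable"))

#' Serialize results to a delimited-table row layout
#'
#' Produces the standard results layout (one row per estimate):
#' `method, n_snps, theta, se, ci_low, ci_high, p, OR, OR_low, OR_high`.
#' MR-Egger estimates yield two rows (slope plus an intercept row whose
#' OR columns hold the exponentiated intercept, an odds); MR-PRESSO results
#' yield raw and corrected rows.  Lists of estimates are row-bound.
#'
#' @param x an estimate object or a list of them.
#' @param ... unused.
#' @return data.frame.
#' @export
setGeneric("resultsTable", function(x, ...) standardGeneric("resultsTable"))
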