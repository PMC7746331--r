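# Accessor and show methods.

#' @describeIn MRData number of instruments J.
#' @param x,object an MRData object.
#' @export
setMethod("nSnps", "MRData", function(x) length(x@snpIds))

#' @describeIn MRData variant identifiers.
#' @export
setMethod("snpIds", "MRData", function(x) x@snpIds)

#' @describeIn MRData exposure trait label.
#' @export
setMethod("traitName", "MRData", function(x) x@traitName)

#' @describeIn MRData exposure unit descriptor.
#' @export
setMethod("exposureScale", "MRData", function(x) x@exposureScale)

#' @describeIn MRData SNP-exposure coefficients.
#' @export
setMethod("betaExposure", "MRData", function(x) x@betaExposure)

#' @describeIn MRData standard errors of the SNP-exposure coefficients.
#' @export
setMethod("seExposure", "MRData", function(x) x@seExposure)

#' @describeIn MRData SNP-outcome coefficients.
#' @export
setMethod("betaOutcome", "MRData", function(x) x@betaOutcome)

#' @describeIn MRData standard errors of the SNP-outcome coefficients.
#' @export
setMethod("seOutcome", "MRData", function(x) x@seOutcome)

#' Subset an MRData object by variant
#'
#' @param x an [MRData-class] object.
#' @param i integer, logical, or character (rsid) index.
#' @param j,...,drop ignored.
#' @return An [MRData-class] with the selected variants.
#' @export
setMethod("[", "MRData", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@snpIds)
  MRData(x@snpIds[i], x@betaExposure[i], x@seExposure[i],
         x@betaOutcome[i], x@seOutcome[i], x@traitName, x@exposureScale)
})

#' Coerce MRData to a data.frame
#'
#' @param x an [MRData-class] object.
#' @param ... unused.
#' @return data.frame with one row per variant.
#' @export
setMethod("as.data.frame", "MRData", function(x, ...) {
  data.frame(rsid = x@snpIds,
             beta_exposure = x@betaExposure, se_exposure = x@seExposure,
             beta_outcome = x@betaOutcome, se_outcome = x@seOutcome,
             stringsAsFactors = FALSE)
})

setMethod("show", "MRData", function(object) {
  cat(sprintf("MRData: %d instrument(s) for trait '%s' (%s)\n",
              length(object@snpIds), object@traitName, object@exposureScale))
  df <- as.data.frame(object)
  print(utils::head(df, 6), row.names = FALSE)
  if (nrow(df) > 6) cat(sprintf("  ... and %d more variants\n", nrow(df) - 6L))
  invisible(NULL)
})

#' @describeIn MREstimate estimator name.
#' @param x,object an MREstimate object.
#' @export
setMethod("methodName", "MREstimate", function(x) x@method)

#' @describeIn MREstimate causal effect on the log-OR scale.
#' @export
setMethod("theta", "MREstimate", function(x) x@theta)

#' @describeIn MREstimate standard error of the estimate.
#' @export
setMethod("stdError", "MREstimate", function(x) x@se)

#' @describeIn MREstimate 95% confidence bounds, `c(low, high)`.
#' @export
setMethod("confInt", "MREstimate", function(x) c(x@ciLow, x@ciHigh))

#' @describeIn MREstimate two-sided p-value.
#' @export
setMethod("pValue", "MREstimate", function(x) x@pvalue)

#' @describeIn MREstimate number of instruments used.
#' @export
setMethod("nSnps", "MREstimate", function(x) x@nSnps)

#' @describeIn MREstimate odds ratio of the outcome with its 95% CI,
#'   `exp(c(theta, ciLow, ciHigh))`.
#' @export
setMethod("oddsRatio", "MREstimate", function(x) {
  c(OR = exp(x@theta), OR_low = exp(x@ciLow), OR_high = exp(x@ciHigh))
})

setMethod("show", "MREstimate", function(object) {
  or <- oddsRatio(object)
  cat(sprintf("%s estimate (%d SNPs)\n", object@method, object@nSnps))
  cat(sprintf("  theta = %.4f (se %.4f), 95%% CI %.4f to %.4f, p = %.3g\n",
              object@theta, object@se, object@ciLow, object@ciHigh,
              object@pvalue))
  cat(sprintf("  OR = %.2f (%.2f-%.2f)\n", or[1], or[2], or[3]))
  invisible(NULL)
})

#' @describeIn MREggerEstimate intercept estimate with se, CI, p-value and
#'   odds-scale view.
#' @param x,object an MREggerEstimate object.
#' @export
setMethod("eggerIntercept", "MREggerEstimate", function(x) {
  list(estimate = x@intercept, se = x@interceptSE,
       ciLow = x@interceptCILow, ciHigh = x@interceptCIHigh,
       pvalue = x@interceptPValue,
       odds = c(odds = exp(x@intercept), odds_low = exp(x@interceptCILow),
                odds_high = exp(x@interceptCIHigh)))
})

setMethod("show", "MREggerEstimate", function(object) {
  callNextMethod()
  cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g  [directional pleiotropy test]\n",
              object@intercept, object@interceptSE, object@interceptPValue))
  invisible(NULL)
})

#' @describeIn MRPressoResult observed global residual sum of squares.
#' @param x,object an MRPressoResult object.
#' @export
setMethod("globalRSS", "MRPressoResult", function(x) x@globalRSS)

#' @describeIn MRPressoResult Monte-Carlo p-value of the global test.
#' @export
setMethod("globalPValue", "MRPressoResult", function(x) x@globalP)

#' @describeIn MRPressoResult indices of flagged variants.
#' @export
setMethod("outlierIndices", "MRPressoResult", function(x) x@outlierIndices)

#' @describeIn MRPressoResult IVW estimate after outlier removal.
#' @export
setMethod("correctedEstimate", "MRPressoResult", function(x) x@corrected)

#' @describeIn MRPressoResult distortion-test p-value.
#' @export
setMethod("distortionPValue", "MRPressoResult", function(x) x@distortionP)

#' @describeIn MRPressoResult per-variant outlier report.
#' @export
setMethod("outlierTable", "MRPressoResult", function(x) {
  data.frame(rsid = x@snpIds,
             contribution = x@contributions,
             p_adjusted = x@outlierPValues,
             flagged = seq_along(x@snpIds) %in% x@outlierIndices,
             stringsAsFactors = FALSE)
})

setMethod("show", "MRPressoResult", function(object) {
  cat(sprintf("MR-PRESSO (%d SNPs, %d simulations, seed %d)\n",
              length(object@snpIds), object@nSim, object@seed))
  cat(sprintf("  global test: RSS = %.3f, p = %.3g\n",
              object@globalRSS, object@globalP))
  if (length(object@outlierIndices)) {
    cat(sprintf("  outliers: %s\n",
                paste(object@snpIds[object@outlierIndices], collapse = ", ")))
    cat(sprintf("  distortion test p = %.3g\n", object@distortionP))
  } else cat("  no outliers flagged\n")
  if (object@allFlagged) {
    cat("  every variant flagged; corrected estimate undefined\n")
  } else {
    or <- oddsRatio(object@corrected)
    cat(sprintf("  corrected IVW: OR = %.2f (%.2f-%.2f), p = %.3g\n",
                or[1], or[2], or[3], object@corrected@pvalue))
  }
  invisible(NULL)
})

#' @describeIn MRHeterogeneity upper-tail chi-square p-value.
#' @param x,object an MRHeterogeneity object.
#' @export
setMethod("pValue", "MRHeterogeneity", function(x) x@pvalue)

setMethod("show", "MRHeterogeneity", function(object) {
  cat(sprintf("Cochran's Q = %.2f on %d df, p = %.3g\n",
              object@q, object@df, object@pvalue))
  invisible(NULL)
})

setMethod("show", "MRSimConfig", function(object) {
  cat(sprintf("Synthetic two-sample design: J = %d, true effect %.3f, pleiotropy '%s'\n",
              object@nSnps, object@thetaTrue, object@pleiotropyMode))
  if (object@pleiotropyMode != "none")
    cat(sprintf("  alpha ~ N(%.3f, %.3f) on %.0f%% of variants, InSIDE violation %.2f\n",
                if (object@pleiotropyMode == "balanced") 0 else object@pleiotropyMean,
                object@pleiotropySd, 100 * object@invalidFraction,
                object@insideViolation))
  cat(sprintf("  seed %d\n", object@seed))
  invisible(NULL)
})

.estimateRow <- function(est) {
  data.frame(method = est@method, n_snps = est@nSnps, theta = est@theta,
             se = est@se, ci_low = est@ciLow, ci_high = est@ciHigh,
             p = est@pvalue, OR = exp(est@theta), OR_low = exp(est@ciLow),
             OR_high = exp(est@ciHigh), stringsAsFactors = FALSE)
}

#' @describeIn resultsTable one row.
#' @export
setMethod("resultsTable", "MREstimate", function(x, ...) .estimateRow(x))

#' @describeIn resultsTable slope row plus intercept row (odds scale).
#' @export
setMethod("resultsTable", "MREggerEstimate", function(x, ...) {
  rows <- .estimateRow(x)
  rows <- rbind(rows, data.frame(
    method = paste0(x@method, " (intercept)"), n_snps = x@nSnps,
    theta = x@intercept, se = x@interceptSE, ci_low = x@interceptCILow,
    ci_high = x@interceptCIHigh, p = x@interceptPValue,
    OR = exp(x@intercept), OR_low = exp(x@interceptCILow),
    OR_high = exp(x@interceptCIHigh), stringsAsFactors = FALSE))
  rows
})

#' @describeIn resultsTable raw and corrected rows.
#' @export
setMethod("resultsTable", "MRPressoResult", function(x, ...) {
  rows <- .estimateRow(x@raw)
  rows$method <- "MR-PRESSO (raw)"
  if (!x@allFlagged) {
    corr <- .estimateRow(x@corrected)
    corr$method <- "MR-PRESSO"
    rows <- rbind(corr, rows)
  }
  rows
})

#' @describeIn resultsTable row-bind a list of estimates.
#' @export
setMethod("resultsTable", "list", function(x, ...) {
  do.call(rbind, c(lapply(x, resultsTable), list(make.row.names = FALSE)))
})
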