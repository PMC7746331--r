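# Heterogeneity, influence, and per-variant diagnostics.

#' Cochran's Q heterogeneity test
#'
#' Q = sum_j w_j (theta_j - theta_IVW)^2, with theta_j the per-variant ratio
#' estimates, w_j the inverse squared first-order ratio standard errors
#' (bx_j^2 / sy_j^2), and theta_IVW the fixed-effects IVW estimate (the
#' standard definitional centre, regardless of which IVW variant is reported
#' as the headline estimate).  Under homogeneity Q is approximately
#' chi-square with J - 1 degrees of freedom.
#'
#' @param data an [MRData-class] object (J >= 2).
#' @return An [MRHeterogeneity-class].
#' @export
cochranQ <- function(data) {
  stopifnot(is(data, "MRData"))
  J <- .checkMinSnps(data, 2L, "Cochran's Q")
  q <- .cochranQ(data@betaExposure, data@betaOutcome, data@seOutcome)
  df <- J - 1L
  new("MRHeterogeneity", q = q, df = df,
      pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

.ESTIMATOR_REGISTRY <- list(
  ivw = list(fun = function(data, ...) mrIVW(data), min = 1L),
  ivw_fixed = list(fun = function(data, ...) mrIVW(data, model = "fixed"),
                   min = 1L),
  ivw_penalized_robust = list(
    fun = function(data, penaltyScale = 20, robustTuning = 1.345, ...)
      mrIVWRobust(data, penaltyScale, robustTuning), min = 3L),
  mr_egger = list(fun = function(data, ...) mrEgger(data), min = 3L),
  simple_median = list(
    fun = function(data, nBoot = 1000, seed = 1, ...)
      mrSimpleMedian(data, nBoot, seed), min = 3L),
  weighted_median = list(
    fun = function(data, nBoot = 1000, seed = 1, ...)
      mrWeightedMedian(data, nBoot, seed), min = 3L),
  weighted_mbe = list(
    fun = function(data, phi = 1, nBoot = 1000, seed = 1, ...)
      mrWeightedMBE(data, phi, nBoot, seed), min = 3L),
  mr_presso = list(
    fun = function(data, nSim = 1000, outlierThreshold = 0.05, seed = 1, ...)
      mrPresso(data, nSim, outlierThreshold, seed), min = 4L)
)

.resolveEstimator <- function(method) {
  entry <- .ESTIMATOR_REGISTRY[[method]]
  if (is.null(entry))
    stop("unknown estimator '", method, "'; available: ",
         paste(names(.ESTIMATOR_REGISTRY), collapse = ", "))
  entry
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect J times, each time excluding one variant,
#' to expose single-instrument influence.  The returned table has J + 1
#' rows: one per excluded variant plus the all-variant estimate
#' (`excluded = "(none)"`).  Rows whose confidence interval excludes the
#' full-set point estimate are flagged as influential.
#'
#' @param data an [MRData-class] object (J >= 3).
#' @param method estimator name (default `"ivw"`); one of
#'   ivw, ivw_fixed, ivw_penalized_robust, mr_egger, simple_median,
#'   weighted_median, weighted_mbe.
#' @param ... estimator parameters (e.g. `nBoot`, `seed`, `phi`).
#' @return data.frame with columns excluded, n_snps, theta, se, ci_low,
#'   ci_high, p, influential.
#' @export
leaveOneOut <- function(data, method = "ivw", ...) {
  stopifnot(is(data, "MRData"))
  J <- .checkMinSnps(data, 3L, "leave-one-out analysis")
  entry <- .resolveEstimator(method)
  if (J - 1L < entry$min)
    stop(sprintf("leave-one-out with '%s' needs J - 1 >= %d instruments",
                 method, entry$min))
  fitRow <- function(d, label) {
    est <- tryCatch(entry$fun(d, ...), error = function(e)
      stop(sprintf("estimator failed with '%s' excluded: %s",
                   label, conditionMessage(e)), call. = FALSE))
    data.frame(excluded = label, n_snps = est@nSnps, theta = est@theta,
               se = est@se, ci_low = est@ciLow, ci_high = est@ciHigh,
               p = est@pvalue, stringsAsFactors = FALSE)
  }
  full <- fitRow(data, "(none)")
  rows <- lapply(seq_len(J), function(j) fitRow(data[-j], data@snpIds[j]))
  out <- rbind(full, do.call(rbind, rows))
  out$influential <- !is.na(out$ci_low) &
    (full$theta < out$ci_low | full$theta > out$ci_high)
  rownames(out) <- NULL
  out
}

#' Per-variant effect table for scatter and forest displays
#'
#' One row per variant with the exposure and outcome coefficients, their
#' standard errors, the 95% confidence bounds of the outcome coefficient,
#' and the fitted causal slope for overlay (constant across rows).
#'
#' @param data an [MRData-class] object.
#' @param est an [MREstimate-class] whose slope to overlay.
#' @return data.frame with columns rsid, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome, ci_low, ci_high, slope.
#' @export
variantEffectTable <- function(data, est) {
  stopifnot(is(data, "MRData"), is(est, "MREstimate"))
  data.frame(rsid = data@snpIds,
             beta_exposure = data@betaExposure,
             se_exposure = data@seExposure,
             beta_outcome = data@betaOutcome,
             se_outcome = data@seOutcome,
             ci_low = data@betaOutcome - .Z975 * data@seOutcome,
             ci_high = data@betaOutcome + .Z975 * data@seOutcome,
             slope = est@theta,
             stringsAsFactors = FALSE)
}
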