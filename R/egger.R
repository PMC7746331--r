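# MR-Egger regression.

#' MR-Egger regression
#'
#' The same weighted linear regression as IVW but with the intercept left
#' free: beta_outcome ~ intercept + slope * beta_exposure, weighted by the
#' inverse variance of the outcome associations.  The slope is a causal
#' estimate that remains consistent under directional pleiotropy provided
#' instrument strength is independent of the direct effects (InSIDE); the
#' intercept estimates the average direct (pleiotropic) effect per variant,
#' and an intercept different from zero indicates directional pleiotropy.
#'
#' Exposure coefficients are oriented positive internally (see
#' [orientPositive()]); the Egger intercept is not invariant to allele
#' coding, so a common orientation is required.  Standard errors carry the
#' multiplicative random-effects inflation max(1, sqrt(Q'/(J-2))), where Q'
#' is the weighted residual sum of squares; inference uses the t
#' distribution with J - 2 degrees of freedom.
#'
#' @param data an [MRData-class] object (J >= 3, non-constant exposure
#'   coefficients, none zero).
#' @return An [MREggerEstimate-class]; the inherited slots hold the slope.
#' @examples
#' d <- MRData(paste0("rs", 1:3), c(0.1, 0.2, 0.3), rep(0.01, 3),
#'             0.01 + 0.5 * c(0.1, 0.2, 0.3), rep(0.02, 3))
#' est <- mrEgger(d)
#' theta(est)                # 0.5
#' eggerIntercept(est)$estimate  # 0.01
#' @export
mrEgger <- function(data) {
  stopifnot(is(data, "MRData"))
  J <- .checkMinSnps(data, 3L, "MR-Egger")
  data <- orientPositive(data)
  bx <- data@betaExposure; by <- data@betaOutcome; sy <- data@seOutcome
  if (stats::sd(bx) == 0)
    stop("MR-Egger is unidentified: all exposure coefficients identical")
  w <- 1 / sy^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  V <- solve(XtWX)
  est <- unname(drop(V %*% crossprod(X, w * by)))
  resid <- by - drop(X %*% est)
  qPrime <- sum(w * resid^2)
  df <- J - 2L
  scale <- max(1, sqrt(qPrime / df))
  modelSE <- unname(sqrt(diag(V))) * scale
  tcrit <- stats::qt(0.975, df)
  pvals <- 2 * stats::pt(-abs(est / modelSE), df)

  new("MREggerEstimate",
      method = "MR-Egger", theta = est[2], se = modelSE[2],
      ciLow = est[2] - tcrit * modelSE[2],
      ciHigh = est[2] + tcrit * modelSE[2],
      pvalue = pvals[2], nSnps = as.integer(J),
      intercept = est[1], interceptSE = modelSE[1],
      interceptCILow = est[1] - tcrit * modelSE[1],
      interceptCIHigh = est[1] + tcrit * modelSE[1],
      interceptPValue = pvals[1])
}
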