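# Ratio estimates and the inverse-variance weighted estimators.

.Z975 <- stats::qnorm(0.975)

.newEstimate <- function(method, theta, se, J, ciLow = NULL, ciHigh = NULL,
                         pvalue = NULL) {
  if (is.na(se)) {
    ciLow <- ciHigh <- pvalue <- NA_real_
  } else {
    if (is.null(ciLow)) ciLow <- theta - .Z975 * se
    if (is.null(ciHigh)) ciHigh <- theta + .Z975 * se
    if (is.null(pvalue)) pvalue <- 2 * stats::pnorm(-abs(theta / se))
  }
  new("MREstimate", method = method, theta = theta, se = se,
      ciLow = ciLow, ciHigh = ciHigh, pvalue = pvalue, nSnps = as.integer(J))
}

.checkMinSnps <- function(data, min, what) {
  J <- length(data@snpIds)
  if (J < min)
    stop(sprintf("%s requires at least %d instruments (got %d)", what, min, J))
  J
}

#' Per-variant ratio (Wald) estimates
#'
#' The per-instrument causal estimate theta_j = beta_outcome / beta_exposure
#' with its first-order standard error se_outcome / |beta_exposure| (the
#' no-measurement-error convention, treating SNP-exposure coefficients as
#' known).  With `secondOrder = TRUE` the exposure-side uncertainty is
#' propagated: se^2 = se_Y^2/bx^2 + se_X^2 by^2 / bx^4.
#'
#' @param data an [MRData-class] object; no exposure coefficient may be zero.
#' @param secondOrder include the exposure-side variance term.
#' @return data.frame with columns `rsid`, `theta`, `se`.
#' @examples
#' d <- MRData("rs1", 0.2, 0.01, 0.1, 0.05)
#' ratioEstimates(d)  # theta 0.5, se 0.25
#' @export
ratioEstimates <- function(data, secondOrder = FALSE) {
  stopifnot(is(data, "MRData"))
  zero <- data@betaExposure == 0
  if (any(zero))
    stop("zero exposure coefficient for variant(s): ",
         paste(data@snpIds[zero], collapse = ", "))
  bx <- data@betaExposure; by <- data@betaOutcome
  sx <- data@seExposure; sy <- data@seOutcome
  se <- if (secondOrder) sqrt(sy^2 / bx^2 + sx^2 * by^2 / bx^4)
        else sy / abs(bx)
  data.frame(rsid = data@snpIds, theta = by / bx, se = se,
             stringsAsFactors = FALSE)
}

# closed-form IVW sums; shared by estimators and diagnostics
.ivwTheta <- function(bx, by, sy) {
  sum(bx * by / sy^2) / sum(bx^2 / sy^2)
}

.cochranQ <- function(bx, by, sy, theta0 = NULL) {
  if (is.null(theta0)) theta0 <- .ivwTheta(bx, by, sy)
  w <- (bx / sy)^2
  sum(w * (by / bx - theta0)^2)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of the SNP-outcome coefficients on the SNP-exposure
#' coefficients through the origin, weighted by the inverse variance of the
#' outcome associations:
#' theta = sum(bx by / sy^2) / sum(bx^2 / sy^2).
#' Under the fixed-effects model se = sqrt(1 / sum(bx^2/sy^2)); under the
#' multiplicative random-effects model (the default, conservative under
#' heterogeneity) the fixed se is inflated by max(1, sqrt(Q/(J-1))) where Q
#' is Cochran's Q.  The point estimate is identical under both models.
#'
#' @param data an [MRData-class] object (J >= 1).
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An [MREstimate-class].
#' @examples
#' d <- MRData(paste0("rs", 1:3), c(0.1, 0.2, 0.3), rep(0.01, 3),
#'             c(0.02, 0.05, 0.09), c(0.01, 0.01, 0.02))
#' mrIVW(d)
#' @export
mrIVW <- function(data, model = c("random", "fixed")) {
  stopifnot(is(data, "MRData"))
  model <- match.arg(model)
  J <- .checkMinSnps(data, 1L, "IVW")
  bx <- data@betaExposure; by <- data@betaOutcome; sy <- data@seOutcome
  theta <- .ivwTheta(bx, by, sy)
  seFixed <- sqrt(1 / sum(bx^2 / sy^2))
  se <- seFixed
  if (model == "random" && J >= 2L) {
    q <- .cochranQ(bx, by, sy, theta)
    se <- seFixed * max(1, sqrt(q / (J - 1)))
  }
  .newEstimate(if (model == "fixed") "IVW (fixed-effects)" else "IVW",
               theta, se, J)
}

#' Penalized robust inverse-variance weighted estimator
#'
#' IVW made resistant to heterogeneous and outlying instruments in two
#' steps.  First, each variant's inverse-variance weight is multiplied by
#' min(1, penaltyScale * q_j) where q_j is the upper-tail chi-square(1)
#' probability of the variant's heterogeneity contribution at the plain IVW
#' estimate, so instruments with extreme ratio estimates are down-weighted.
#' Second, the causal effect is re-estimated by bounded-influence (Huber)
#' regression through the origin with the penalized weights, and the
#' standard error is inflated by the robust residual scale as in the
#' multiplicative random-effects model.
#'
#' @param data an [MRData-class] object (J >= 3).
#' @param penaltyScale multiplier on the per-variant heterogeneity tail
#'   probability; default 20.
#' @param robustTuning Huber tuning constant; default 1.345.
#' @return An [MREstimate-class].
#' @export
mrIVWRobust <- function(data, penaltyScale = 20, robustTuning = 1.345) {
  stopifnot(is(data, "MRData"))
  if (penaltyScale <= 0) stop("penaltyScale must be > 0")
  if (robustTuning <= 0) stop("robustTuning must be > 0")
  J <- .checkMinSnps(data, 3L, "penalized robust IVW")
  bx <- data@betaExposure; by <- data@betaOutcome; sy <- data@seOutcome
  w <- (bx / sy)^2
  theta0 <- .ivwTheta(bx, by, sy)
  qContrib <- w * (by / bx - theta0)^2
  pen <- stats::pchisq(qContrib, df = 1, lower.tail = FALSE)
  wPen <- w * pmin(1, penaltyScale * pen)

  # equivalently: WLS of by on bx through the origin with per-variant
  # inverse variances pen_j / sy_j^2
  thetaWls <- sum(wPen * (by / bx)) / sum(wPen)
  seBase <- sqrt(1 / sum(wPen))
  if (max(abs(by - thetaWls * bx)) < 1e-12) {
    # exact fit: robust regression degenerate, residual scale factor 1
    return(.newEstimate("Penalized robust IVW", thetaWls, seBase, J))
  }
  invVar <- wPen / bx^2
  fit <- suppressWarnings(
    MASS::rlm(by ~ bx - 1, weights = invVar, wt.method = "inv.var",
              psi = MASS::psi.huber, k = robustTuning, maxit = 200))
  theta <- unname(stats::coef(fit)[1])
  scale <- max(1, fit$s)
  se <- sqrt(1 / sum(invVar * bx^2)) * scale
  .newEstimate("Penalized robust IVW", theta, se, J)
}
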