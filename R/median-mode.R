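# Median-based and mode-based estimators with parametric-bootstrap standard
# errors.

# weighted median by linear interpolation of the cumulative standardized
# weight s_j = sum_{k<=j} w_k - w_j/2 against the sorted values
.weightedMedian <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  n <- length(x)
  if (0.5 >= s[n]) return(x[n])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

# mode of the weighted gaussian-kernel density of the ratio estimates;
# bandwidth h = phi * 0.9 * min(weighted sd, weighted scaled MAD) * J^(-1/5),
# density evaluated on a 512-point grid over [min - 3h, max + 3h], ties in
# the maximum broken by the smallest grid index
.weightedMode <- function(th, w, phi) {
  w <- w / sum(w)
  mu <- sum(w * th)
  # ratios equal up to rounding: the density is a point mass
  if (diff(range(th)) <= 1e-12 * max(1, abs(mu)))
    return(.weightedMedian(th, w))
  sdw <- sqrt(sum(w * (th - mu)^2))
  madw <- 1.4826 * .weightedMedian(abs(th - .weightedMedian(th, w)), w)
  s <- min(sdw, madw)
  if (s <= 0) s <- max(sdw, madw)
  if (s <= 0) return(.weightedMedian(th, w))
  h <- phi * 0.9 * s * length(th)^(-1 / 5)
  d <- stats::density(th, weights = w, bw = h, kernel = "gaussian",
                      from = min(th) - 3 * h, to = max(th) + 3 * h, n = 512)
  d$x[which.max(d$y)]
}

# parametric bootstrap: redraw exposure and outcome coefficients around their
# observed values with their standard errors, recompute the point estimate
.bootstrapSE <- function(data, pointFun, nBoot, seed) {
  if (nBoot == 0L) return(NA_real_)
  set.seed(seed)
  J <- length(data@snpIds)
  bxMat <- matrix(stats::rnorm(J * nBoot, data@betaExposure, data@seExposure),
                  nrow = J)
  byMat <- matrix(stats::rnorm(J * nBoot, data@betaOutcome, data@seOutcome),
                  nrow = J)
  ests <- vapply(seq_len(nBoot),
                 function(i) pointFun(bxMat[, i], byMat[, i], data@seOutcome),
                 numeric(1))
  stats::sd(ests)
}

.bootEstimate <- function(data, method, pointFun, nBoot, seed, minSnps = 3L) {
  stopifnot(is(data, "MRData"))
  J <- .checkMinSnps(data, minSnps, method)
  if (nBoot < 0L) stop("nBoot must be >= 0")
  if (nBoot > 0L && (missing(seed) || is.null(seed) || is.na(seed)))
    stop("a seed is required for the parametric bootstrap")
  thetaHat <- pointFun(data@betaExposure, data@betaOutcome, data@seOutcome)
  se <- .bootstrapSE(data, pointFun, as.integer(nBoot),
                     if (nBoot > 0L) as.integer(seed) else 0L)
  .newEstimate(method, thetaHat, se, J)
}

#' Simple median estimator
#'
#' The median of the per-variant ratio estimates (midpoint interpolation for
#' even J).  Consistent when at least half of the instruments are valid.
#' The standard error comes from a parametric bootstrap that redraws both
#' exposure and outcome coefficients from normal distributions centred at
#' their observed values with their standard errors; results are
#' deterministic given `seed`.
#'
#' @param data an [MRData-class] object (J >= 3).
#' @param nBoot bootstrap replicates (default 1000); `0` skips the bootstrap
#'   and returns the point estimate with `NA` se/CI/p.
#' @param seed integer RNG seed (required when `nBoot > 0`).
#' @return An [MREstimate-class].
#' @export
mrSimpleMedian <- function(data, nBoot = 1000, seed = NULL) {
  .bootEstimate(data, "Simple median",
                function(bx, by, sy) stats::median(by / bx),
                nBoot, seed)
}

#' Weighted median estimator
#'
#' The inverse-variance weighted median of the per-variant ratio estimates:
#' variants are sorted by ratio, weights w_j = bx_j^2 / sy_j^2 are
#' standardized to sum 1, and the estimate is the linear interpolation of
#' the sorted ratios against the cumulative weight sum(w_k, k <= j) - w_j/2
#' at 0.5.  Consistent when at least half of the total weight comes from
#' valid instruments, giving robustness to up to 50% invalid instruments.
#' Bootstrap standard error as in [mrSimpleMedian()].
#'
#' @inheritParams mrSimpleMedian
#' @return An [MREstimate-class].
#' @export
mrWeightedMedian <- function(data, nBoot = 1000, seed = NULL) {
  .bootEstimate(data, "Weighted median",
                function(bx, by, sy) .weightedMedian(by / bx, (bx / sy)^2),
                nBoot, seed)
}

#' Weighted mode-based estimator
#'
#' The mode of the inverse-variance weighted empirical density of the
#' per-variant ratio estimates: a gaussian-kernel density with weights
#' proportional to the inverse squared first-order ratio standard errors and
#' modified-Silverman bandwidth h = phi * 0.9 * min(sd*, mad*) * J^(-1/5)
#' (sd* and mad* the weighted standard deviation and scaled
#' median-absolute-deviation of the ratios), evaluated on a 512-point grid
#' spanning the ratio range plus or minus 3h.  Ties in the density maximum
#' resolve to the smallest grid point.  Consistent when the largest group of
#' instruments sharing a common ratio is valid, giving robustness to
#' horizontal pleiotropy.  Bootstrap standard error as in
#' [mrSimpleMedian()].
#'
#' @inheritParams mrSimpleMedian
#' @param phi bandwidth multiplier, > 0; default 1.
#' @return An [MREstimate-class].
#' @export
mrWeightedMBE <- function(data, phi = 1, nBoot = 1000, seed = NULL) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0)
    stop("phi must be a positive number")
  .bootEstimate(data, "Weighted MBE",
                function(bx, by, sy) .weightedMode(by / bx, (bx / sy)^2, phi),
                nBoot, seed)
}
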