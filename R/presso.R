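# MR-PRESSO: global heterogeneity test, per-variant outlier test,
# outlier-corrected estimate, and distortion test, all by Monte-Carlo
# simulation.

# leave-one-out fixed-effects IVW estimates, O(J) via the closed-form sums
.looThetas <- function(bx, by, sy) {
  a <- bx * by / sy^2
  b <- bx^2 / sy^2
  (sum(a) - a) / (sum(b) - b)
}

# simulate nSim null datasets: coefficients redrawn around (bx_j,
# thetaLoo_j * bx_j) with sds (sx_j, sy_j); leave-one-out expected values
# recomputed within each simulated dataset.  Consumes the RNG stream.
.pressoSim <- function(data, thetaLoo, nSim) {
  bx <- data@betaExposure; sx <- data@seExposure
  sy <- data@seOutcome
  J <- length(bx)
  bxStar <- matrix(stats::rnorm(J * nSim, bx, sx), nrow = J)
  byStar <- matrix(stats::rnorm(J * nSim, thetaLoo * bx, sy), nrow = J)
  a <- bxStar * byStar / sy^2
  b <- bxStar^2 / sy^2
  thetaLooStar <- (rep(colSums(a), each = J) - a) /
                  (rep(colSums(b), each = J) - b)
  contrib <- ((byStar - thetaLooStar * bxStar) / sy)^2
  list(rss = colSums(contrib), contrib = contrib)
}

.pressoObserved <- function(data) {
  bx <- data@betaExposure; by <- data@betaOutcome; sy <- data@seOutcome
  thetaLoo <- .looThetas(bx, by, sy)
  contrib <- ((by - thetaLoo * bx) / sy)^2
  list(thetaLoo = thetaLoo, contrib = contrib, rss = sum(contrib))
}

#' Monte-Carlo null distribution of the MR-PRESSO global statistic
#'
#' Exposes the simulated null residual-sum-of-squares vector underlying the
#' global test, mainly for diagnostics and testing.
#'
#' @param data an [MRData-class] object (J >= 4).
#' @param thetaLoo optional per-variant leave-one-out IVW estimates; computed
#'   from `data` when NULL.
#' @param nSim number of simulations, >= 1.
#' @param seed integer RNG seed.
#' @return numeric vector of `nSim` simulated standardized RSS values.
#' @export
pressoNullDistribution <- function(data, thetaLoo = NULL, nSim = 1000,
                                   seed = 1) {
  stopifnot(is(data, "MRData"))
  .checkMinSnps(data, 4L, "MR-PRESSO")
  if (!is.numeric(nSim) || length(nSim) != 1L || nSim < 1)
    stop("nSim must be a positive count")
  if (is.null(thetaLoo))
    thetaLoo <- .looThetas(data@betaExposure, data@betaOutcome,
                           data@seOutcome)
  set.seed(as.integer(seed))
  .pressoSim(data, thetaLoo, as.integer(nSim))$rss
}

#' MR-PRESSO outlier test and correction
#'
#' For each variant j the expected outcome coefficient is
#' thetaLoo_j * bx_j, with thetaLoo_j the fixed-effects IVW estimate
#' excluding j; the observed global statistic is the sum of squared
#' outcome-standardized residuals.  Its null distribution is built by
#' redrawing, `nSim` times, exposure and outcome coefficients around
#' (bx_j, thetaLoo_j bx_j) with sds (sx_j, sy_j) and recomputing the
#' statistic.  The global p-value is the Monte-Carlo tail probability
#' (1 + exceedances) / (nSim + 1); per-variant p-values test each variant's
#' contribution the same way and are Bonferroni adjusted across J.  Variants
#' with adjusted p below `outlierThreshold` are flagged; the corrected
#' estimate is the IVW estimate (multiplicative random effects) on the
#' remaining variants.  The distortion test compares the observed raw-vs-
#' corrected difference with its distribution when equally many randomly
#' chosen variants are removed.
#'
#' All randomness is governed by `seed`; results are reproducible.
#'
#' @param data an [MRData-class] object (J >= 4).
#' @param nSim Monte-Carlo replicates for the global/outlier tests
#'   (default 1000).
#' @param outlierThreshold significance level on the Bonferroni-adjusted
#'   per-variant p-values (default 0.05).
#' @param seed integer RNG seed.
#' @param nDistortion draws for the distortion test (default 1000).
#' @return An [MRPressoResult-class].
#' @export
mrPresso <- function(data, nSim = 1000, outlierThreshold = 0.05, seed = 1,
                     nDistortion = 1000) {
  stopifnot(is(data, "MRData"))
  J <- .checkMinSnps(data, 4L, "MR-PRESSO")
  if (!is.numeric(nSim) || length(nSim) != 1L || nSim < 1)
    stop("nSim must be a positive count")
  nSim <- as.integer(nSim); seed <- as.integer(seed)

  obs <- .pressoObserved(data)
  set.seed(seed)
  sim <- .pressoSim(data, obs$thetaLoo, nSim)

  globalP <- (1 + sum(sim$rss >= obs$rss)) / (nSim + 1)
  pRaw <- (1 + rowSums(sim$contrib >= obs$contrib)) / (nSim + 1)
  pAdj <- pmin(1, J * pRaw)
  outliers <- which(pAdj < outlierThreshold)

  raw <- mrIVW(data)
  allFlagged <- length(outliers) == J
  corrected <- NULL
  distortionP <- NA_real_
  if (!allFlagged) {
    corrected <- if (length(outliers)) mrIVW(data[-outliers]) else raw
    if (length(outliers)) {
      dObs <- corrected@theta - raw@theta
      bx <- data@betaExposure; by <- data@betaOutcome; sy <- data@seOutcome
      dSim <- vapply(seq_len(nDistortion), function(i) {
        drop <- sample.int(J, length(outliers))
        .ivwTheta(bx[-drop], by[-drop], sy[-drop]) - raw@theta
      }, numeric(1))
      distortionP <- (1 + sum(abs(dSim) >= abs(dObs))) / (nDistortion + 1)
    }
  }

  new("MRPressoResult",
      snpIds = data@snpIds, globalRSS = obs$rss, globalP = globalP,
      contributions = obs$contrib, outlierPValues = pAdj,
      outlierIndices = as.integer(outliers), raw = raw,
      corrected = corrected, distortionP = distortionP,
      nSim = nSim, seed = seed, allFlagged = allFlagged)
}
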