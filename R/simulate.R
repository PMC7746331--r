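# Synthetic two-sample summary statistics with known causal effect and
# controllable pleiotropy.

#' Build a synthetic-study configuration
#'
#' Defaults describe a glycemic-trait-sized instrument set against a binary
#' disease outcome: 30 instruments, SNP-exposure effects around 0.05 trait
#' units with sd 0.02 (truncated at |beta| >= 0.01 to avoid weak-instrument
#' degeneracy in ratio estimates), exposure standard errors of a few
#' thousandths (large-consortium quantitative GWAS), outcome log-OR standard
#' errors of 0.02-0.05 (case-control GWAS of tens of thousands), and a
#' causal effect of 0.3 log-odds per exposure unit.
#'
#' @param nSnps number of instruments J (default 30).
#' @param thetaTrue causal effect on the log-OR scale (default 0.3).
#' @param exposureEffectMean,exposureEffectSd distribution of true
#'   SNP-exposure effects (default 0.05, 0.02), truncated at
#'   absolute value >= 0.01.
#' @param seExposureRange,seOutcomeRange uniform (lo, hi) ranges for the
#'   per-variant standard errors; defaults (0.002, 0.005) and (0.02, 0.05).
#' @param pleiotropyMode `"none"` (default), `"balanced"`, or
#'   `"directional"`.
#' @param pleiotropySd sd of the per-variant direct effects alpha_j
#'   (default 0.05).
#' @param pleiotropyMean mean of alpha_j (default 0; forced to 0 under
#'   `"balanced"`).
#' @param invalidFraction share of variants receiving pleiotropy, in [0,1]
#'   (default 0 under `"none"`, otherwise set it explicitly).
#' @param insideViolation correlation between alpha_j and the true exposure
#'   effects; 0 (default) satisfies the InSIDE assumption.
#' @param seed integer RNG seed (required).
#' @return An [MRSimConfig-class].
#' @export
simConfig <- function(nSnps = 30, thetaTrue = 0.3,
                      exposureEffectMean = 0.05, exposureEffectSd = 0.02,
                      seExposureRange = c(0.002, 0.005),
                      seOutcomeRange = c(0.02, 0.05),
                      pleiotropyMode = c("none", "balanced", "directional"),
                      pleiotropySd = 0.05, pleiotropyMean = 0,
                      invalidFraction = 0, insideViolation = 0, seed = 1) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  new("MRSimConfig",
      nSnps = as.integer(nSnps), thetaTrue = as.numeric(thetaTrue),
      exposureEffectMean = as.numeric(exposureEffectMean),
      exposureEffectSd = as.numeric(exposureEffectSd),
      seExposureRange = as.numeric(seExposureRange),
      seOutcomeRange = as.numeric(seOutcomeRange),
      pleiotropyMode = pleiotropyMode,
      pleiotropySd = as.numeric(pleiotropySd),
      pleiotropyMean = as.numeric(pleiotropyMean),
      invalidFraction = as.numeric(invalidFraction),
      insideViolation = as.numeric(insideViolation),
      seed = as.integer(seed))
}

# truncated-normal exposure effects: resample any |x| < bound
.truncatedEffects <- function(n, mean, sd, bound = 0.01) {
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:100) {
    bad <- abs(x) < bound
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x[abs(x) < bound] <- bound * sign(x[abs(x) < bound] + (x[abs(x) < bound] == 0))
  x
}

#' Simulate a harmonized two-sample summary dataset
#'
#' Draws, in a fixed documented order under `set.seed(config@seed)`:
#' true exposure effects (truncated normal), per-variant exposure and
#' outcome standard errors (uniform), the invalid-variant subset, direct
#' effects alpha_j, and finally observation noise for the exposure and the
#' outcome coefficients.  True outcome effects are
#' thetaTrue * betaExposure_true + alpha_j (alpha_j = 0 for valid
#' variants).  Identical configurations produce identical datasets.
#'
#' @param config an [MRSimConfig-class] from [simConfig()].
#' @return list with `data` (an [MRData-class]) and `truth` (list:
#'   thetaTrue, trueBetaExposure, trueBetaOutcome, alpha, invalid index
#'   vector).
#' @examples
#' sim <- simulateSummaryData(simConfig(nSnps = 10, seed = 7))
#' theta(mrIVW(sim$data))
#' @export
simulateSummaryData <- function(config) {
  stopifnot(is(config, "MRSimConfig"))
  validObject(config)
  J <- config@nSnps
  set.seed(config@seed)
  trueBx <- .truncatedEffects(J, config@exposureEffectMean,
                              config@exposureEffectSd)
  sx <- stats::runif(J, config@seExposureRange[1], config@seExposureRange[2])
  sy <- stats::runif(J, config@seOutcomeRange[1], config@seOutcomeRange[2])

  alpha <- numeric(J)
  invalid <- integer(0)
  if (config@pleiotropyMode != "none" && config@invalidFraction > 0 &&
      config@pleiotropySd >= 0) {
    nInvalid <- round(config@invalidFraction * J)
    invalid <- if (nInvalid > 0) sort(sample.int(J, nInvalid)) else integer(0)
    if (length(invalid)) {
      mu <- if (config@pleiotropyMode == "balanced") 0 else config@pleiotropyMean
      rho <- config@insideViolation
      z <- stats::rnorm(length(invalid))
      sdx <- config@exposureEffectSd
      standardizedBx <- if (sdx > 0)
        (trueBx[invalid] - config@exposureEffectMean) / sdx else 0
      alpha[invalid] <- mu + config@pleiotropySd *
        (rho * standardizedBx + sqrt(1 - rho^2) * z)
    }
  }
  trueBy <- config@thetaTrue * trueBx + alpha
  bx <- stats::rnorm(J, trueBx, sx)
  by <- stats::rnorm(J, trueBy, sy)

  ids <- sprintf("rs%05d", seq_len(J))
  list(data = MRData(ids, bx, sx, by, sy,
                     traitName = "synthetic exposure"),
       truth = list(thetaTrue = config@thetaTrue,
                    trueBetaExposure = trueBx, trueBetaOutcome = trueBy,
                    alpha = alpha, invalid = invalid))
}

.NONPALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))

#' Write synthetic exposure and outcome summary tables
#'
#' Emits the dataset of [simulateSummaryData()] as a pair of
#' summary-statistics files in the [readSummaryTable()] layout, with random
#' (non-palindromic) allele labels and allele frequencies.  With
#' `alleleScramble = TRUE` a random subset of outcome rows has its allele
#' labels swapped, beta negated, and frequency complemented — an encoding
#' change that [harmonize()] must undo exactly, so harmonizing the two files
#' reproduces the generated dataset either way.
#'
#' @param config an [MRSimConfig-class].
#' @param dir output directory (created if needed).
#' @param alleleScramble randomly swap allele labels on outcome rows.
#' @return list with `exposure` and `outcome` (file paths), `data`, `truth`.
#' @export
simulateStudyTables <- function(config, dir = tempfile("mrsim"),
                                alleleScramble = FALSE) {
  sim <- simulateSummaryData(config)
  d <- sim$data
  J <- length(d@snpIds)
  # allele labelling consumes the stream after the dataset draws
  pair <- .NONPALINDROMIC_PAIRS[sample.int(nrow(.NONPALINDROMIC_PAIRS), J,
                                           replace = TRUE), , drop = FALSE]
  eaf <- stats::runif(J, 0.1, 0.9)
  fmt <- function(x) sprintf("%.17g", x)
  zP <- function(b, s) 2 * stats::pnorm(-abs(b / s))

  expTab <- data.frame(rsid = d@snpIds, effect_allele = pair[, 1],
                       other_allele = pair[, 2], eaf = fmt(eaf),
                       beta = fmt(d@betaExposure), se = fmt(d@seExposure),
                       pvalue = fmt(zP(d@betaExposure, d@seExposure)),
                       stringsAsFactors = FALSE)
  swap <- if (alleleScramble) stats::runif(J) < 0.5 else rep(FALSE, J)
  outTab <- data.frame(rsid = d@snpIds,
                       effect_allele = ifelse(swap, pair[, 2], pair[, 1]),
                       other_allele = ifelse(swap, pair[, 1], pair[, 2]),
                       eaf = fmt(ifelse(swap, 1 - eaf, eaf)),
                       beta = fmt(ifelse(swap, -d@betaOutcome, d@betaOutcome)),
                       se = fmt(d@seOutcome),
                       pvalue = fmt(zP(d@betaOutcome, d@seOutcome)),
                       stringsAsFactors = FALSE)

  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- file.path(dir, c("exposure.tsv", "outcome.tsv"))
  for (i in 1:2) {
    tab <- list(expTab, outTab)[[i]]
    ok <- tryCatch({
      utils::write.table(tab, paths[i], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) stop("failed writing ", paths[i], ": ",
                                conditionMessage(e)))
  }
  list(exposure = paths[1], outcome = paths[2],
       data = sim$data, truth = sim$truth)
}
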