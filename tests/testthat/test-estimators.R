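# The seven causal estimators.

test_that("ratio estimates follow the first-order definition", {
  d <- makeData(0.2, 0.1, 0.05)
  r <- ratioEstimates(d)
  expect_equal(r$theta, 0.5)
  expect_equal(r$se, 0.25)
  dNeg <- makeData(-0.2, 0.1, 0.05)
  expect_equal(ratioEstimates(dNeg)$theta, -0.5)
  expect_equal(ratioEstimates(dNeg)$se, 0.25)

  d10 <- randomData(10, seed = 101)
  r10 <- ratioEstimates(d10)
  expect_equal(r10$theta, betaOutcome(d10) / betaExposure(d10))
  expect_equal(r10$se, seOutcome(d10) / abs(betaExposure(d10)))
  # second-order option adds the exposure-side term
  r2 <- ratioEstimates(d10, secondOrder = TRUE)
  expect_true(all(r2$se > r10$se))
  expect_error(ratioEstimates(makeData(c(0.1, 0), c(1, 1), c(1, 1))), "rs2")
})

test_that("IVW matches a weighted-regression oracle and collapses correctly", {
  # single instrument: the ratio estimate itself
  d1 <- makeData(1, 0.3, 0.1)
  e1f <- mrIVW(d1, model = "fixed")
  e1r <- mrIVW(d1)
  expect_equal(theta(e1f), 0.3)
  expect_equal(stdError(e1f), 0.1)
  expect_equal(theta(e1r), 0.3)
  expect_equal(stdError(e1r), 0.1)

  # homogeneous ratios: exact estimate, random-effects scale factor 1
  dh <- homogeneousData(0.42, J = 6)
  expect_equal(theta(mrIVW(dh)), 0.42)
  expect_equal(stdError(mrIVW(dh)), stdError(mrIVW(dh, model = "fixed")))

  # 3-SNP toy against the lm() oracle
  d3 <- makeData(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.09), c(0.01, 0.01, 0.02))
  o <- oracleIVW(d3)
  ef <- mrIVW(d3, model = "fixed")
  expect_equal(theta(ef), o$theta, tolerance = 1e-10)
  expect_equal(stdError(ef), o$seFixed, tolerance = 1e-10)
  expect_equal(theta(mrIVW(d3)), o$theta, tolerance = 1e-10)
})

test_that("random-effects IVW only widens the standard error", {
  for (s in 1:10) {
    d <- randomData(15, seed = 200 + s)
    ef <- mrIVW(d, model = "fixed"); er <- mrIVW(d)
    expect_identical(theta(ef), theta(er))
    expect_gte(stdError(er), stdError(ef))
  }
})

test_that("penalized robust IVW reduces to IVW on homogeneous data", {
  dh <- homogeneousData(0.42, J = 8)
  expect_equal(theta(mrIVWRobust(dh)), theta(mrIVW(dh)), tolerance = 1e-8)
  expect_error(mrIVWRobust(homogeneousData(0.3, J = 2)), "at least 3")
  expect_error(mrIVWRobust(homogeneousData(0.3, J = 5), penaltyScale = -1),
               "penaltyScale")
})

test_that("penalized robust IVW resists a gross outlier better than IVW", {
  nRep <- 200
  errRobust <- errIVW <- numeric(nRep)
  for (r in seq_len(nRep)) {
    sim <- simulateSummaryData(simConfig(nSnps = 20, seed = 3000 + r))
    d <- sim$data
    # displace one variant's ratio by 10 outcome-standard-errors
    k <- 1 + (r %% 20)
    by <- betaOutcome(d)
    by[k] <- by[k] + 10 * seOutcome(d)[k]
    d <- MRData(snpIds(d), betaExposure(d), seExposure(d), by, seOutcome(d))
    errRobust[r] <- abs(theta(mrIVWRobust(d)) - 0.3)
    errIVW[r] <- abs(theta(mrIVW(d)) - 0.3)
  }
  # the outlier shifts IVW by ~2 of its standard errors, so shared sampling
  # noise still lets IVW land closer in a minority of replicates; the
  # aggregate error must shrink decisively and the robust fit win a clear
  # majority of head-to-head comparisons
  expect_lt(mean(errRobust), 0.6 * mean(errIVW))
  expect_lt(median(errRobust), median(errIVW))
  expect_gte(mean(errRobust < errIVW), 0.6)
})

test_that("MR-Egger recovers exact linear data and matches the lm oracle", {
  bx <- c(0.1, 0.2, 0.3)
  d <- makeData(bx, 0.01 + 0.5 * bx, rep(0.02, 3))
  est <- mrEgger(d)
  expect_equal(theta(est), 0.5, tolerance = 1e-10)
  ic <- eggerIntercept(est)
  expect_equal(ic$estimate, 0.01, tolerance = 1e-10)
  # zero residuals: no random-effects inflation of the model-based se
  w <- 1 / seOutcome(d)^2
  X <- cbind(1, bx)
  V <- solve(t(X) %*% (w * X))
  expect_equal(stdError(est), sqrt(V[2, 2]), tolerance = 1e-10)
  expect_equal(ic$se, sqrt(V[1, 1]), tolerance = 1e-10)

  for (s in 1:5) {
    dr <- randomData(12, seed = 400 + s)
    co <- oracleEgger(dr)
    er <- mrEgger(dr)
    expect_equal(eggerIntercept(er)$estimate, co[1], tolerance = 1e-10)
    expect_equal(theta(er), co[2], tolerance = 1e-10)
  }
  expect_error(mrEgger(homogeneousData(0.3, J = 2)), "at least 3")
  expect_error(mrEgger(homogeneousData(0.3, bx = rep(0.1, 4))),
               "identical")
})

test_that("median estimators interpolate as defined", {
  dOdd <- makeData(rep(0.1, 3), 0.1 * c(0.1, 0.5, 0.9), rep(0.02, 3))
  expect_equal(theta(mrSimpleMedian(dOdd, nBoot = 0)), 0.5)
  dEven <- makeData(rep(0.1, 4), 0.1 * c(0.05, 0.2, 0.4, 0.8), rep(0.02, 4))
  expect_equal(theta(mrSimpleMedian(dEven, nBoot = 0)), 0.3)

  # equal weights reduce the weighted median to the simple median (odd J)
  expect_equal(theta(mrWeightedMedian(dOdd, nBoot = 0)), 0.5)

  # hand-computed cumulative-weight interpolation: ratios (0.1, 0.5, 0.9),
  # weights (0.8, 0.1, 0.1) -> s = (0.4, 0.85, 0.95); at 0.5:
  # 0.1 + (0.5-0.4)/(0.85-0.4) * (0.5-0.1) = 0.18888...
  sy <- 0.02
  bx <- sy * sqrt(c(0.8, 0.1, 0.1))  # so bx^2/sy^2 are the desired weights
  dW <- makeData(bx, bx * c(0.1, 0.5, 0.9), rep(sy, 3))
  est <- theta(mrWeightedMedian(dW, nBoot = 0))
  expect_equal(est, 0.1 + (0.5 - 0.4) / (0.85 - 0.4) * 0.4, tolerance = 1e-10)
  expect_lt(est, 0.5)

  expect_error(mrSimpleMedian(makeData(0.1, 0.05, 0.02), nBoot = 0),
               "at least 3")
})

test_that("bootstrap standard errors are deterministic under a seed", {
  d <- randomData(10, seed = 77)
  a <- mrSimpleMedian(d, nBoot = 200, seed = 42)
  b <- mrSimpleMedian(d, nBoot = 200, seed = 42)
  expect_identical(theta(a), theta(b))
  expect_identical(stdError(a), stdError(b))
  c1 <- mrWeightedMBE(d, nBoot = 200, seed = 9)
  c2 <- mrWeightedMBE(d, nBoot = 200, seed = 9)
  expect_identical(stdError(c1), stdError(c2))
  expect_error(mrSimpleMedian(d, nBoot = 100), "seed")
})

test_that("the mode-based estimate finds the majority cluster", {
  # point mass: every ratio equal
  dEq <- homogeneousData(0.37, J = 6)
  for (phi in c(0.25, 1, 4))
    expect_equal(theta(mrWeightedMBE(dEq, phi = phi, nBoot = 0)), 0.37,
                 tolerance = 1e-6)

  # bimodal: 7 tight ratios near 0.5, 3 near 2.0, equal weights
  set.seed(5)
  ratios <- c(0.5 + rnorm(7, 0, 0.01), 2.0 + rnorm(3, 0, 0.01))
  bx <- rep(0.1, 10); sy <- rep(0.02, 10)
  dBi <- makeData(bx, bx * ratios, sy)
  est <- theta(mrWeightedMBE(dBi, nBoot = 0))
  expect_lt(abs(est - 0.5), 0.1)
  # agreement with the brute-force dense-grid kernel oracle
  oracle <- oracleMode(ratios, (bx / sy)^2)
  expect_equal(est, oracle, tolerance = 1e-2)

  expect_error(mrWeightedMBE(dEq, phi = 0, nBoot = 0), "phi")
})

test_that("the odds-ratio view exponentiates the estimate and CI", {
  z <- qnorm(0.975)
  mk <- function(th, se) new("MREstimate", method = "IVW", theta = th,
                             se = se, ciLow = th - z * se, ciHigh = th + z * se,
                             pvalue = 0.5, nSnps = 5L)
  expect_equal(unname(oddsRatio(mk(0, 0.1))[1]), 1.0)
  or <- oddsRatio(mk(0.2852, 0.1216))
  expect_equal(unname(or), c(1.33, 1.05, 1.69), tolerance = 0.01)
  expect_true(all(or > 0))
  # CI bounds widen monotonically with se
  or2 <- oddsRatio(mk(0.2852, 0.2))
  expect_lt(or2["OR_low"], or["OR_low"])
  expect_gt(or2["OR_high"], or["OR_high"])
})

test_that("estimators are scale- and sign-equivariant and collapse at J = 1", {
  for (s in 1:5) {
    d <- randomData(12, seed = 600 + s)
    cst <- 2.5
    dScaled <- MRData(snpIds(d), cst * betaExposure(d), cst * seExposure(d),
                      betaOutcome(d), seOutcome(d))
    dNeg <- MRData(snpIds(d), betaExposure(d), seExposure(d),
                   -betaOutcome(d), seOutcome(d))
    fits <- list(
      function(x) theta(mrIVW(x)),
      function(x) theta(mrIVWRobust(x)),
      function(x) theta(mrEgger(x)),
      function(x) theta(mrSimpleMedian(x, nBoot = 0)),
      function(x) theta(mrWeightedMedian(x, nBoot = 0)),
      function(x) theta(mrWeightedMBE(x, nBoot = 0)))
    for (f in fits) {
      expect_equal(f(dScaled), f(d) / cst, tolerance = 1e-6)
      expect_equal(f(dNeg), -f(d), tolerance = 1e-6)
    }
    expect_equal(eggerIntercept(mrEgger(dNeg))$estimate,
                 -eggerIntercept(mrEgger(d))$estimate, tolerance = 1e-10)
  }
  d1 <- makeData(0.2, 0.1, 0.05)
  expect_equal(theta(mrIVW(d1)), 0.5)
  expect_error(mrSimpleMedian(d1, nBoot = 0), "at least 3")
  expect_error(mrWeightedMedian(d1, nBoot = 0), "at least 3")
  expect_error(mrWeightedMBE(d1, nBoot = 0), "at least 3")
})

test_that("results tables carry the standard columns, Egger adding an intercept row", {
  d <- randomData(10, seed = 900)
  tab <- resultsTable(list(mrIVW(d), mrEgger(d)))
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("method", "n_snps", "theta", "se", "ci_low", "ci_high",
                    "p", "OR", "OR_low", "OR_high") %in% names(tab)))
  expect_equal(tab$OR, exp(tab$theta))
  expect_true("MR-Egger (intercept)" %in% tab$method)
})
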