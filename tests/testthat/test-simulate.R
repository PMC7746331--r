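# Synthetic two-sample summary-statistics generator.

test_that("configurations validate before any sampling", {
  expect_error(simConfig(nSnps = 0), "nSnps")
  expect_error(simConfig(seExposureRange = c(0.01, 0.001)), "ordered")
  expect_error(simConfig(seOutcomeRange = c(-0.1, 0.1)), "positive")
  expect_error(simConfig(invalidFraction = 1.5), "invalidFraction")
  expect_error(simConfig(insideViolation = 2), "insideViolation")
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- simConfig(nSnps = 25, seed = 99, pleiotropyMode = "balanced",
                   invalidFraction = 0.4)
  a <- simulateSummaryData(cfg)
  b <- simulateSummaryData(cfg)
  expect_identical(betaExposure(a$data), betaExposure(b$data))
  expect_identical(betaOutcome(a$data), betaOutcome(b$data))
  expect_identical(a$truth, b$truth)
  c <- simulateSummaryData(simConfig(nSnps = 25, seed = 100))
  expect_false(identical(betaOutcome(a$data), betaOutcome(c$data)))
})

test_that("exposure effects stay clear of zero and truth is recorded", {
  sim <- simulateSummaryData(simConfig(nSnps = 200, seed = 17,
                                       exposureEffectMean = 0,
                                       exposureEffectSd = 0.02))
  expect_true(all(abs(sim$truth$trueBetaExposure) >= 0.01))
  expect_equal(sim$truth$trueBetaOutcome,
               0.3 * sim$truth$trueBetaExposure + sim$truth$alpha)
  expect_length(sim$truth$invalid, 0L)
})

test_that("IVW recovers a null and a strong causal effect from the generator", {
  nRep <- 200
  covered <- logical(nRep)
  for (r in seq_len(nRep)) {
    sim <- simulateSummaryData(simConfig(nSnps = 30, thetaTrue = 0,
                                         seed = 9000 + r))
    est <- mrIVW(sim$data)
    covered[r] <- abs(theta(est)) <= 3 * stdError(est)
  }
  expect_gte(mean(covered), 0.95)

  simTight <- simulateSummaryData(simConfig(
    nSnps = 100, thetaTrue = 0.3, seed = 424,
    seExposureRange = c(1e-4, 2e-4), seOutcomeRange = c(1e-4, 2e-4)))
  expect_lt(abs(theta(mrIVW(simTight$data)) - 0.3), 0.01)
})

test_that("study tables round-trip through harmonization, scrambled or not", {
  for (scramble in c(FALSE, TRUE)) {
    sim <- simulateStudyTables(simConfig(nSnps = 6, seed = 31),
                               alleleScramble = scramble)
    expo <- readSummaryTable(sim$exposure)
    outc <- readSummaryTable(sim$outcome)
    expect_equal(nrow(expo), 6L)
    expect_equal(nrow(outc), 6L)
    h <- harmonize(expo, outc)
    expect_equal(snpIds(h$data), snpIds(sim$data))
    expect_equal(betaExposure(h$data), betaExposure(sim$data))
    expect_equal(betaOutcome(h$data), betaOutcome(sim$data))
    expect_equal(seOutcome(h$data), seOutcome(sim$data))
  }
})

test_that("directional pleiotropy biases IVW while the Egger intercept tracks its mean", {
  nRep <- 150
  interceptOK <- logical(nRep); ivwBiased <- logical(nRep)
  for (r in seq_len(nRep)) {
    sim <- simulateSummaryData(simConfig(
      nSnps = 200, seed = 20000 + r, pleiotropyMode = "directional",
      pleiotropyMean = 0.02, pleiotropySd = 0.01, invalidFraction = 1,
      insideViolation = 0))
    eg <- mrEgger(sim$data)
    ic <- eggerIntercept(eg)
    interceptOK[r] <- abs(ic$estimate - 0.02) <= 3 * ic$se
    est <- mrIVW(sim$data)
    ivwBiased[r] <- abs(theta(est) - 0.3) > 3 * stdError(est)
  }
  expect_gte(mean(interceptOK), 0.95)
  expect_gte(mean(ivwBiased), 0.95)
})

test_that("under balanced pleiotropy the robust estimators match or beat IVW", {
  nRep <- 150
  errs <- matrix(NA_real_, nRep, 4,
                 dimnames = list(NULL, c("ivw", "smed", "wmed", "mbe")))
  for (r in seq_len(nRep)) {
    sim <- simulateSummaryData(simConfig(
      nSnps = 30, seed = 21000 + r, pleiotropyMode = "balanced",
      pleiotropySd = 0.1, invalidFraction = 0.4))
    d <- sim$data
    errs[r, ] <- abs(c(theta(mrIVW(d)),
                       theta(mrSimpleMedian(d, nBoot = 0)),
                       theta(mrWeightedMedian(d, nBoot = 0)),
                       theta(mrWeightedMBE(d, nBoot = 0))) - 0.3)
  }
  mae <- apply(errs, 2, median)
  expect_lte(mae["wmed"], mae["ivw"])
  expect_lte(mae["mbe"], mae["ivw"])
})
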