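# Allele harmonization and orientation.

test_that("swapped outcome alleles flip the outcome beta", {
  expo <- assocRow("rs1", "A", "G", 0.30, 0.10, 0.010)
  outc <- assocRow("rs1", "G", "A", 0.70, -0.05, 0.020)
  h <- harmonize(expo, outc)
  expect_equal(betaOutcome(h$data), 0.05)
  expect_equal(h$report$disposition, "flipped")
})

test_that("strand-complemented alleles are recognized, in both orientations", {
  expo <- rbind(assocRow("rs1", "A", "G", 0.30, 0.10, 0.010),
                assocRow("rs2", "C", "A", 0.20, 0.08, 0.010))
  outc <- rbind(assocRow("rs1", "T", "C", 0.30, 0.04, 0.020),  # complement, same order
                assocRow("rs2", "T", "G", 0.80, -0.03, 0.020)) # complement, swapped
  h <- harmonize(expo, outc)
  expect_equal(betaOutcome(h$data), c(0.04, 0.03))
  expect_equal(h$report$disposition, c("kept", "flipped"))
})

test_that("variants absent from the outcome are dropped with a reason", {
  expo <- rbind(assocRow("rs1", "A", "G", 0.3, 0.10, 0.01),
                assocRow("rs2", "C", "T", 0.4, 0.05, 0.01))
  outc <- assocRow("rs1", "A", "G", 0.3, 0.02, 0.02)
  h <- harmonize(expo, outc)
  expect_equal(snpIds(h$data), "rs1")
  expect_equal(h$report$reason[h$report$rsid == "rs2"],
               "not found in outcome")
})

test_that("irreconcilable allele pairs are dropped, never silently kept", {
  expo <- rbind(assocRow("rs1", "A", "C", 0.3, 0.10, 0.01),
                assocRow("rs2", "A", "G", 0.3, 0.10, 0.01))
  outc <- rbind(assocRow("rs1", "A", "G", 0.3, 0.02, 0.02),
                assocRow("rs2", "A", "G", 0.3, 0.02, 0.02))
  h <- harmonize(expo, outc)
  expect_equal(snpIds(h$data), "rs2")
  expect_equal(h$report$reason[h$report$rsid == "rs1"], "allele mismatch")
})

test_that("palindromic variants follow the configured policy", {
  expoAmb <- assocRow("rs3", "A", "T", 0.49, 0.10, 0.01)
  expoClear <- assocRow("rs4", "C", "G", 0.10, 0.10, 0.01)
  outcAmb <- assocRow("rs3", "A", "T", 0.49, 0.05, 0.02)
  outcSame <- assocRow("rs4", "C", "G", 0.12, 0.05, 0.02)
  outcOtherStrand <- assocRow("rs4", "C", "G", 0.88, 0.05, 0.02)

  # ambiguous frequency window drops under infer_by_eaf
  h <- harmonize(rbind(expoAmb, expoClear), rbind(outcAmb, outcSame),
                 "infer_by_eaf", eafThreshold = 0.42, traitName = "t")
  expect_true(grepl("ambiguous", h$report$reason[1]))

  # clear frequencies orient: concordant minor allele -> kept as-is
  h2 <- harmonize(rbind(expoAmb, expoClear), rbind(outcAmb, outcSame))
  expect_equal(snpIds(h2$data), "rs4")
  expect_equal(betaOutcome(h2$data), 0.05)

  # discordant minor allele -> strand flip
  h3 <- harmonize(expoClear, outcOtherStrand)
  expect_equal(betaOutcome(h3$data), -0.05)

  # drop policy removes all palindromic variants
  expoPlain <- assocRow("rs5", "A", "G", 0.2, 0.09, 0.01)
  outcPlain <- assocRow("rs5", "A", "G", 0.2, 0.03, 0.02)
  h4 <- harmonize(rbind(expoAmb, expoClear, expoPlain),
                  rbind(outcAmb, outcSame, outcPlain),
                  palindromicPolicy = "drop")
  expect_equal(snpIds(h4$data), "rs5")
  expect_equal(h4$report$reason[1:2], c("palindromic", "palindromic"))
  # keep policy assumes same strand and aligns by label
  h5 <- harmonize(expoClear, outcSame, palindromicPolicy = "keep")
  expect_equal(betaOutcome(h5$data), 0.05)
})

test_that("harmonization reports reconcile and the operation is idempotent", {
  set.seed(42)
  sim <- simulateStudyTables(simConfig(nSnps = 12, seed = 11),
                             alleleScramble = TRUE)
  expo <- readSummaryTable(sim$exposure)
  outc <- readSummaryTable(sim$outcome)
  h <- harmonize(expo, outc)
  expect_equal(nrow(h$report), nrow(expo))
  expect_equal(sum(h$report$disposition %in% c("kept", "flipped")) +
               sum(h$report$disposition == "dropped"), nrow(expo))

  # re-harmonizing the already-aligned pair changes nothing
  aligned <- expo
  aligned$beta <- betaOutcome(h$data)[match(aligned$rsid, snpIds(h$data))]
  aligned$se <- seOutcome(h$data)[match(aligned$rsid, snpIds(h$data))]
  h2 <- harmonize(expo, aligned)
  expect_equal(betaOutcome(h2$data), betaOutcome(h$data))
  expect_true(all(h2$report$disposition == "kept"))
})

test_that("ratio estimates are invariant under allele re-labeling", {
  expo <- rbind(assocRow("rs1", "A", "G", 0.3, 0.10, 0.01),
                assocRow("rs2", "C", "T", 0.8, -0.07, 0.02))
  outc <- rbind(assocRow("rs1", "A", "G", 0.3, 0.05, 0.02),
                assocRow("rs2", "C", "T", 0.8, 0.04, 0.03))
  base <- harmonize(expo, outc)$data
  # relabel rs2 in the exposure study: swap alleles, negate beta, flip eaf
  expoFlip <- expo
  expoFlip[2, c("effect_allele", "other_allele")] <- expo[2, c("other_allele", "effect_allele")]
  expoFlip$beta[2] <- -expo$beta[2]
  expoFlip$eaf[2] <- 1 - expo$eaf[2]
  relab <- harmonize(expoFlip, outc)$data
  expect_equal(betaOutcome(relab) / betaExposure(relab),
               betaOutcome(base) / betaExposure(base))
})

test_that("orientPositive flips pairs, preserves ratios, rejects zero effects", {
  d <- makeData(c(0.2, -0.1, 0.05), c(0.06, 0.02, -0.01), rep(0.02, 3))
  o <- orientPositive(d)
  expect_true(all(betaExposure(o) > 0))
  expect_equal(betaExposure(o)[2], 0.1)
  expect_equal(betaOutcome(o)[2], -0.02)
  expect_equal(betaOutcome(o) / betaExposure(o),
               betaOutcome(d) / betaExposure(d))
  # all-positive input is unchanged
  expect_equal(orientPositive(o), o)
  dz <- makeData(c(0.2, 0), c(0.06, 0.02), rep(0.02, 2))
  expect_error(orientPositive(dz), "rs2")
})
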