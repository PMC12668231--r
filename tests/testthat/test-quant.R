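test_that("noise-free mixing system matches the least-squares oracle", {
  S <- c(100, 10, 50); P <- c(10, 100, 50); T <- c(205, 70, 125)
  oracle <- lsMixingOracle(T, S, P)
  expect_equal(unname(oracle), c(2, 0.5), tolerance = 1e-10)

  fit <- estimateMixingRatios(T, S, P, minCount = 5,
                              priors = priorConfig(ratioFamily = "flat"),
                              seed = 1)
  est <- mixingRatios(fit)
  expect_lt(abs(est[["aS"]] - oracle[["aS"]]) / oracle[["aS"]], 0.01)
  expect_lt(abs(est[["aP"]] - oracle[["aP"]]) / oracle[["aP"]], 0.01)
  expect_equal(fit@nGenesUsed, 3L)
})

test_that("degenerate equal-split data resolve along the prior ridge with a warning", {
  T <- rep(1000L, 20); S <- rep(500L, 20); P <- rep(500L, 20)
  expect_warning(fit <- estimateMixingRatios(T, S, P, seed = 1),
                 "ridge|constant")
  est <- mixingRatios(fit)
  ## prior centred at 1 resolves aS + aP = 2 symmetrically
  expect_equal(unname(est[["aS"]]), 1, tolerance = 0.05)
  expect_equal(unname(est[["aP"]]), 1, tolerance = 0.05)
})

test_that("mixing estimates rescale with fraction-wise count scaling, pSup invariant", {
  tx <- simulateTranscriptome(300, seed = 2)
  truth <- simulateTruePSup(tx, sigmaG = 0.3, seed = 3)
  ## noise-free integer-ish counts built directly from the truth
  alpha <- exp(seq(log(50), log(5000), length.out = 300))
  S0 <- round(alpha * truth$true_psup)
  P0 <- round(alpha * (1 - truth$true_psup))
  T0 <- S0 + P0
  flat <- priorConfig(ratioFamily = "flat")
  f1 <- estimateMixingRatios(T0, S0, P0, priors = flat, seed = 1)
  f2 <- estimateMixingRatios(T0, S0 * 3, P0 * 0.2, priors = flat, seed = 1)
  expect_equal(f2@aS, f1@aS / 3, tolerance = 1e-3)
  expect_equal(f2@aP, f1@aP / 0.2, tolerance = 1e-3)
  p1 <- computePSup(S0, P0, f1)$psup
  p2 <- computePSup(S0 * 3, P0 * 0.2, f2)$psup
  expect_equal(p1, p2, tolerance = 1e-3)
})

test_that("count filter feeds the fit and sparse systems error out", {
  T <- c(1000, 1000, 5, 5); S <- c(600, 300, 2, 2); P <- c(300, 600, 2, 2)
  expect_error(estimateMixingRatios(T, S, P, minCount = 20), "filter")
  fit <- estimateMixingRatios(c(T, 1200), c(S, 500), c(P, 500),
                              minCount = 20, seed = 1)
  expect_equal(fit@nGenesUsed, 3L)
  expect_error(estimateMixingRatios(c(-1, T), c(1, S), c(1, P)),
               "non-negative")
})

test_that("simulated experiments recover the programmed mixing ratios", {
  se <- simulateSedSeqExperiment(
    nGenes = 2000, replicates = 1, conditions = c("mock", "stress"),
    depthFactors = c(T = 1, S = 1 / 1.5, P = 1 / 3), seed = 10)
  fits <- estimateMixingRatios(se, seed = 11)
  for (j in seq_along(fits)) {
    expect_lt(abs(fits[[j]]@aS - 1.5) / 1.5, 0.1)
    expect_lt(abs(fits[[j]]@aP - 3.0) / 3.0, 0.15)
  }
})

test_that("posterior mode agrees with MAP within its credible intervals", {
  se <- simulateSedSeqExperiment(nGenes = 500, replicates = 1,
                                 conditions = "mock", seed = 20)
  Tc <- assay(se, "Total")[, 1]; Sc <- assay(se, "Sup")[, 1]
  Pc <- assay(se, "Pellet")[, 1]
  map <- estimateMixingRatios(Tc, Sc, Pc, seed = 1)
  post <- estimateMixingRatios(Tc, Sc, Pc, mode = "posterior", seed = 2,
                               nIter = 2000, burnin = 500)
  ci <- post@posterior$ci95
  expect_true(map@aS >= ci[1, 1] && map@aS <= ci[2, 1])
  expect_true(map@aP >= ci[1, 2] && map@aP <= ci[2, 2])
  expect_identical(post@mode, "posterior")
})

test_that("pSup arithmetic follows the mixing-ratio formula", {
  fit <- makeMixingFit(2, 0.5)
  expect_equal(computePSup(100, 10, fit)$psup, 200 / 205)
  expect_equal(computePSup(50, 50, makeMixingFit(1, 1))$psup, 0.5)
  expect_equal(computePSup(0, 25, fit)$psup, 0)
  expect_true(is.na(computePSup(0, 0, fit)$psup))
  expect_error(computePSup(-5, 10, fit), "non-negative")

  ## expit/logit round trip inside the clipped band
  p <- c(1e-4, 0.01, 0.5, 0.99, 1 - 1e-4)
  expect_equal(expit(logOdds(p)), p, tolerance = 1e-12)
})

test_that("experiment-level pSup assays line up with vector computation", {
  se <- simulateSedSeqExperiment(nGenes = 80, replicates = 2,
                                 conditions = "mock", seed = 30)
  fits <- estimateMixingRatios(se, minCount = 5, seed = 31)
  se <- computePSup(se, fits)
  expect_true(all(c("psup", "lopsup") %in% assayNames(se)))
  byHand <- computePSup(assay(se, "Sup")[, 2], assay(se, "Pellet")[, 2],
                        fits[[2]])
  expect_equal(unname(psup(se)[, 2]), byHand$psup)
  expect_true(all(psup(se) >= 0 & psup(se) <= 1, na.rm = TRUE))
})

test_that("qPCR delta-delta-Cq pSup follows the spike-referenced formula", {
  expect_equal(psupFromCq(20, 18, 20, 18)$psup, 0.5)
  res <- psupFromCq(20, 18, 21, 18)
  expect_equal(res$aSup, 0.25)
  expect_equal(res$aPellet, 0.125)
  expect_equal(res$psup, 2 / 3)
  expect_equal(psupFromCq(20, 18, 20, 18, spikeMassRatio = 10)$psup, 1 / 11)
  expect_error(psupFromCq(20, NA, 21, 18), "spike")
  expect_error(psupFromCq(20, 18, 21, 18, efficiency = 2.5), "efficiency")
})
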