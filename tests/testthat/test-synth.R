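test_that("transcriptome generation is deterministic and respects the induced fraction", {
  a <- simulateTranscriptome(200, fracInduced = 0.1, seed = 7)
  b <- simulateTranscriptome(200, fracInduced = 0.1, seed = 7)
  expect_identical(a, b)
  c <- simulateTranscriptome(200, fracInduced = 0.1, seed = 8)
  expect_false(identical(a, c))

  expect_equal(sum(simulateTranscriptome(1000, fracInduced = 0.05,
                                         seed = 1)$induced), 50)
  expect_equal(sum(simulateTranscriptome(10, fracInduced = 0.29,
                                         seed = 1)$induced), 2)

  expect_error(simulateTranscriptome(0), "nGenes")
  expect_error(simulateTranscriptome(10, fracInduced = 1.5), "fracInduced")
})

test_that("transcript lengths follow the requested log-normal scale", {
  tx <- simulateTranscriptome(5000, lengthLogMean = log(1500),
                              lengthLogSd = 0.5, seed = 3)
  expect_lt(abs(median(tx$length_total) - 1500) / 1500, 0.1)
  expect_true(all(tx$length_total >= 100 & tx$length_total <= 20000))
  expect_true(all(tx$length_total >= tx$utr5_len + tx$utr3_len + 3))
  expect_false(anyDuplicated(tx$gene_id) > 0)
})

test_that("true pSup surface follows the length model arithmetic", {
  tx <- simulateTranscriptome(3, seed = 1)
  tx$length_total <- c(500L, 500L, 500L)
  tx$induced <- FALSE
  p <- simulateTruePSup(tx, beta = 1e-3, x = 1, sigmaG = 0, seed = 1)
  expect_equal(p$true_psup, rep(0.5, 3), tolerance = 1e-12)
  p2 <- simulateTruePSup(tx, beta = 1e-3, x = 1, mu = log(1.5), sigmaG = 0,
                         seed = 1)
  expect_equal(p2$true_psup, rep(0.25, 3), tolerance = 1e-12)
})

test_that("pSup surface is clipped, monotone in length, and jittered to scale", {
  tx <- simulateTranscriptome(5000, seed = 11)
  truth <- simulateTruePSup(tx, sigmaG = 0.3, seed = 12)
  expect_true(all(truth$true_psup >= 0.001 & truth$true_psup <= 0.999))

  ## monotone without jitter/escape
  t0 <- simulateTruePSup(tx, sigmaG = 0, deltaE = 0, seed = 1)
  ord <- order(tx$length_total)
  expect_true(all(diff(t0$true_psup[ord]) <= 1e-12))

  ## empirical logit jitter SD matches sigmaG (deltaE = 0 by default)
  unclipped <- truth$true_psup > 0.001 & truth$true_psup < 0.999
  expect_equal(sd((truth$true_lopsup - logOdds(t0$true_psup, eps = 0))[unclipped]),
               0.3, tolerance = 0.02)

  ## warning when the surface mostly exceeds a sedimented fraction of 1
  expect_warning(simulateTruePSup(tx, beta = 1, x = 1, sigmaG = 0, seed = 1),
                 "clipping")
})

test_that("fraction counts conserve mass in expectation and are reproducible", {
  tx <- simulateTranscriptome(5000, seed = 21)
  truth <- simulateTruePSup(tx, seed = 22)
  sim <- simulateSedSeqCounts(tx, truth, meanTotalCount = 800,
                              depthFactors = c(T = 1, S = 0.5, P = 0.25),
                              phi = 50, seed = 23)
  expect_equal(sim$aS, 2)
  expect_equal(sim$aP, 4)
  resid <- mean(sim$counts$Total - sim$aS * sim$counts$Sup -
                  sim$aP * sim$counts$Pellet)
  expect_lt(abs(resid) / mean(sim$counts$Total), 0.02)

  sim2 <- simulateSedSeqCounts(tx, truth, meanTotalCount = 800,
                               depthFactors = c(T = 1, S = 0.5, P = 0.25),
                               phi = 50, seed = 23)
  expect_identical(sim$counts, sim2$counts)
  sim3 <- simulateSedSeqCounts(tx, truth, meanTotalCount = 800,
                               depthFactors = c(T = 1, S = 0.5, P = 0.25),
                               phi = 50, seed = 24)
  expect_false(identical(sim$counts, sim3$counts))

  expect_error(simulateSedSeqCounts(tx, truth, phi = 0), "phi")
})

test_that("equal depths and pSup 0.5 split counts evenly between fractions", {
  tx <- simulateTranscriptome(5000, seed = 31)
  truth <- simulateTruePSup(tx, seed = 32)
  truth$true_psup[] <- 0.5
  sim <- simulateSedSeqCounts(tx, truth, meanTotalCount = 1000, phi = 1e4,
                              seed = 33)
  expect_equal(mean(sim$counts$Sup) / mean(sim$counts$Total), 0.5,
               tolerance = 0.02)
  expect_equal(mean(sim$counts$Pellet) / mean(sim$counts$Total), 0.5,
               tolerance = 0.02)
})

test_that("simulated experiment container carries truth metadata", {
  se <- simulateSedSeqExperiment(nGenes = 120, replicates = 2, seed = 5)
  expect_s4_class(se, "SedSeqExperiment")
  expect_identical(dim(se), c(120L, 4L))
  expect_setequal(unique(colData(se)$condition), c("mock", "stress"))
  truth <- metadata(se)$truth
  expect_named(truth$psup, c("mock", "stress"))
  expect_length(truth$mixing, 4L)
  ## same master seed reproduces the container exactly
  se2 <- simulateSedSeqExperiment(nGenes = 120, replicates = 2, seed = 5)
  expect_identical(assay(se, "Total"), assay(se2, "Total"))
})

test_that("polysome TPM simulation grounds occupancy in the fractions", {
  tx <- simulateTranscriptome(150, seed = 41)
  tpm <- simulatePolysomeTPM(tx, occupancy = rep(1, 150), nSpikes = 10,
                             seed = 42)
  freeGene <- tpm$tpm[tpm$fraction == "Free" & !tpm$is_spike]
  freeSpike <- tpm$tpm[tpm$fraction == "Free" & tpm$is_spike]
  ## fully occupied transcripts leave the free fraction to the spikes
  expect_lt(sum(freeGene), 0.01 * sum(freeSpike))

  expect_error(simulatePolysomeTPM(tx, rep(0.5, 150), nSpikes = 0), "nSpikes")
  expect_error(simulatePolysomeTPM(tx, rep(1.5, 150)), "occupancy")
  t1 <- simulatePolysomeTPM(tx, rep(0.5, 150), seed = 9)
  t2 <- simulatePolysomeTPM(tx, rep(0.5, 150), seed = 9)
  expect_identical(t1, t2)
})
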