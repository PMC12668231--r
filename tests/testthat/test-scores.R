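test_that("log-odds transform and inverse behave at reference points", {
  expect_equal(logOdds(0.5), 0)
  expect_equal(logOdds(0.9756, eps = 0), log(0.9756 / 0.0244), tolerance = 1e-12)
  expect_error(logOdds(1.2), "outside")
  expect_error(logOdds(-0.1), "outside")
})

test_that("windowed length profile matches a brute-force oracle", {
  set.seed(42)
  n <- 400
  len <- round(exp(runif(n, log(200), log(9000))))
  lop <- rnorm(n, 2 - 0.3 * log(len), 0.4)
  lp <- lengthProfile(lop, len, windowFraction = 0.05)
  oracle <- bruteLengthProfile(lop, len, windowFraction = 0.05)
  expect_equal(lp$mu, oracle$mu, tolerance = 1e-10)
  expect_equal(lp$sigma, oracle$sigma, tolerance = 1e-10)
  expect_equal(lp$sigmaControl, sd(lop - oracle$mu), tolerance = 1e-10)
})

test_that("constant log-odds field gives flat profile and zero residual SD", {
  len <- c(300, 600, 1200, 2400, 4800)
  lp <- suppressWarnings(lengthProfile(rep(1.7, 5), len, windowFraction = 0.3))
  expect_equal(lp$mu, rep(1.7, 5), tolerance = 1e-12)
  expect_equal(lp$sigmaControl, 0, tolerance = 1e-12)
})

test_that("equally spaced log-lengths with a 3-neighbor window give moving averages", {
  len <- exp(seq(5, 9, length.out = 5))
  lop <- c(1, 2, 4, 8, 16)
  ## spacing is 1 log unit over a 4-unit range; window of 0.6*range = 2.4
  ## spans the focal gene plus one neighbor on each side
  lp <- lengthProfile(lop, len, windowFraction = 0.6)
  expect_equal(lp$mu[2:4], c(mean(lop[1:3]), mean(lop[2:4]), mean(lop[3:5])))
  expect_equal(lp$mu[1], mean(lop[1:2]))
  expect_equal(lp$mu[5], mean(lop[4:5]))
})

test_that("widening the window never increases undefined sigma count", {
  set.seed(7)
  len <- round(exp(runif(60, log(150), log(15000))))
  lop <- rnorm(60)
  prev <- suppressWarnings(lengthProfile(lop, len, 0.01))$nUndefinedSigma
  for (w in c(0.02, 0.05, 0.1, 0.4)) {
    cur <- suppressWarnings(lengthProfile(lop, len, w))$nUndefinedSigma
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("delta-Sed identities and arithmetic hold", {
  expect_equal(deltaSed(1.0, -1.0, 0.5), 4.0)
  lop <- rnorm(50)
  expect_true(all(deltaSed(lop, lop, 0.7) == 0))
  ## antisymmetry at fixed sigma
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(deltaSed(a, b, 0.3), -deltaSed(b, a, 0.3))
  expect_error(deltaSed(a, b, 0), "degenerate")
})

test_that("escape score cancels cohort-level shifts and scales residuals", {
  ## gene whose shift equals its cohort mean shift scores 0
  pc <- list(mu = 1, sigma = 0.5, sigmaControl = 0.4, windowFraction = 0.02)
  pt <- list(mu = 0.2, sigma = 0.5, sigmaControl = 0.4, windowFraction = 0.02)
  expect_equal(escapeSed(1.5, 0.7, pc, pt), 0)
  ## residual rise of 0.8 against sigma 0.4 scores 2
  expect_equal(escapeSed(1.5, 1.5, pc, pt), 2)
})

test_that("constant treatment shift moves delta-Sed but not eSed", {
  set.seed(11)
  n <- 300
  len <- round(exp(runif(n, log(200), log(8000))))
  lopC <- rnorm(n, 1, 0.5)
  lopT <- rnorm(n, 0, 0.5)
  pc <- suppressWarnings(lengthProfile(lopC, len))
  pt <- suppressWarnings(lengthProfile(lopT, len))
  const <- 0.9
  ptShift <- suppressWarnings(lengthProfile(lopT + const, len))
  d0 <- deltaSed(lopC, lopT, pc)
  d1 <- deltaSed(lopC, lopT + const, pc)
  expect_equal(d1, d0 - const / pc$sigmaControl, tolerance = 1e-12)
  e0 <- escapeSed(lopC, lopT, pc, pt)
  e1 <- escapeSed(lopC, lopT + const, pc, ptShift)
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("sedScore matches the brute-force sort/bin/Z oracle", {
  set.seed(3)
  n <- 250
  len <- sample(300:8000, n, replace = TRUE)
  ids <- sprintf("g%03d", seq_len(n))
  lop <- cbind(rnorm(n, 1 - len / 4000, 0.5), rnorm(n, 1 - len / 4000, 0.5))
  rownames(lop) <- ids
  oracle <- bruteSedScore(lop, len, ids, binSize = 100)
  got <- sedScore(lop, len, ids, binSize = 100, orientation = "supernatant")
  expect_equal(unname(got), oracle, tolerance = 1e-12)
  ## default orientation flips the sign: positive = sediments more
  sedOri <- sedScore(lop, len, ids, binSize = 100)
  expect_equal(unname(sedOri), -oracle, tolerance = 1e-12)
})

test_that("sedScore bins are standardized and replicates average", {
  set.seed(5)
  n <- 200
  len <- sample(300:9000, n)
  lop <- matrix(rnorm(2 * n), n, 2)
  z <- sedScore(lop[, 1], len, binSize = 100, orientation = "supernatant")
  ord <- order(len, sprintf("%09d", seq_len(n)))
  for (b in 1:2) {
    idx <- ord[((b - 1) * 100 + 1):(b * 100)]
    expect_lt(abs(mean(z[idx])), 1e-9)
    expect_lt(abs(sd(z[idx]) - 1), 1e-9)
  }
  z2 <- sedScore(lop, len, binSize = 100, orientation = "supernatant")
  z1a <- sedScore(lop[, 1], len, binSize = 100, orientation = "supernatant")
  z1b <- sedScore(lop[, 2], len, binSize = 100, orientation = "supernatant")
  expect_equal(z2, (z1a + z1b) / 2, tolerance = 1e-12)
})

test_that("purely length-determined pSup yields null escape and sedScores", {
  set.seed(9)
  n <- 1000
  len <- round(exp(runif(n, log(200), log(10000))))
  lop <- 3 - 0.6 * log(len)   # any monotone function of length
  lp <- lengthProfile(lop, len, windowFraction = 0.02)
  e <- escapeSed(lop, lop, lp, lp)
  ## eSed degenerates to 0/0-free zero shifts: identical conditions cancel
  expect_true(all(abs(e[!is.na(e)]) < 1e-9))
  r <- suppressWarnings(sedScore(lop, len, binSize = 100))
  ## the bin standardization removes any pure length trend: every full
  ## bin of the score is exactly centred
  ord <- order(len, sprintf("%09d", seq_len(n)))
  for (b in seq_len(n %/% 100)) {
    idx <- ord[((b - 1) * 100 + 1):(b * 100)]
    expect_lt(abs(mean(r[idx], na.rm = TRUE)), 1e-9)
  }
})

test_that("condensation scores on identical conditions vanish and stress shows up", {
  se <- simulateSedSeqExperiment(nGenes = 500, replicates = 2, seed = 13)
  fits <- estimateMixingRatios(se, seed = 14)
  se <- computePSup(se, fits)
  scSelf <- suppressWarnings(condensationScores(se, "mock", "mock"))
  expect_true(all(scSelf$delta_sed[!is.na(scSelf$delta_sed)] == 0))

  sc <- suppressWarnings(condensationScores(se, "mock", "stress"))
  expect_gt(median(sc$delta_sed, na.rm = TRUE), 0)
  ind <- rowData(se)$induced
  expect_gt(median(sc$e_sed[ind], na.rm = TRUE),
            median(sc$e_sed[!ind], na.rm = TRUE))
  expect_identical(metadata(sc)$sigmaMode, "global")
})

test_that("transcriptome mean eSed stays near zero without escape offsets", {
  se <- simulateSedSeqExperiment(nGenes = 1500, replicates = 2,
                                 deltaE = 0, inductionLog2fc = 0, seed = 17)
  fits <- estimateMixingRatios(se, seed = 18)
  se <- computePSup(se, fits)
  sc <- suppressWarnings(condensationScores(se, "mock", "stress"))
  expect_lt(abs(mean(sc$e_sed, na.rm = TRUE)), 0.05)
})
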