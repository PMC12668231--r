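makeTpm <- function() {
  data.frame(
    gene_id = rep(c("g1", "g2", "s1", "s2"), times = 3),
    fraction = rep(c("Total", "Free", "Bound"), each = 4),
    tpm = c(10, 20, 4, 6,   2, 16, 4, 6,   8, 4, 4, 6),
    est_counts = rep(500L, 12),
    is_spike = rep(c(FALSE, FALSE, TRUE, TRUE), times = 3),
    stringsAsFactors = FALSE)
}

test_that("spike normalization divides by the per-fraction spike median", {
  tpm <- makeTpm()
  norm <- normalizeToSpikein(tpm)
  ## spike median is 5 in every fraction here
  expect_equal(norm$norm_abundance, tpm$tpm / 5)

  ## scaling one fraction leaves normalized abundances unchanged
  tpm7 <- tpm
  sel <- tpm7$fraction == "Bound"
  tpm7$tpm[sel] <- tpm7$tpm[sel] * 7
  norm7 <- normalizeToSpikein(tpm7)
  expect_equal(norm7$norm_abundance, norm$norm_abundance)

  ## single qualifying spike divides by exactly its abundance
  tpm1 <- tpm[tpm$gene_id != "s2", ]
  norm1 <- normalizeToSpikein(tpm1)
  expect_equal(norm1$norm_abundance[norm1$fraction == "Total"],
               tpm1$tpm[tpm1$fraction == "Total"] / 4)

  ## low-count spikes disqualify and the error names the fraction
  tpmLow <- tpm
  tpmLow$est_counts[tpmLow$is_spike & tpmLow$fraction == "Free"] <- 10L
  expect_error(normalizeToSpikein(tpmLow), "Free")
})

test_that("ribosome occupancy and association follow their ratios", {
  expect_equal(ribosomeOccupancy(3, 3), 0.5)
  expect_equal(ribosomeOccupancy(2, 0), 1.0)
  expect_true(is.na(ribosomeOccupancy(0, 0)))
  expect_error(ribosomeOccupancy(-1, 2), "non-negative")

  expect_equal(ribosomeAssociation(5, 5), 1.0)
  expect_equal(ribosomeAssociation(0, 5), 0.0)
  expect_true(is.na(ribosomeAssociation(5, 0)))
  ## ratio is invariant to joint rescaling
  expect_equal(ribosomeAssociation(6, 4), ribosomeAssociation(6 * 3, 4 * 3))
})

test_that("cushion occupancy applies the EDTA correction", {
  expect_equal(occupancyFromCushion(0.8, 0.1)$occupancy, 0.7)
  expect_equal(occupancyFromCushion(0.8, 0.1, renormalize = TRUE)$occupancy,
               0.7 / 0.9)
  expect_equal(occupancyFromCushion(0.4, 0.4)$occupancy, 0)
  res <- occupancyFromCushion(c(0.5, 0.2), c(0.3, 0.4))
  expect_equal(res$occupancy, c(0.2, 0))
  expect_equal(res$nFloored, 1)
  expect_true(all(res$occupancy >= 0 & res$occupancy <= 1))
  expect_error(occupancyFromCushion(0.5, 1, renormalize = TRUE), "undefined")
  expect_error(occupancyFromCushion(1.2, 0.1), "\\[0, 1\\]")
})

test_that("occupancy survives the polysome simulation round trip", {
  tx <- simulateTranscriptome(400, seed = 1)
  set.seed(99)
  occ <- runif(400)
  tpm <- simulatePolysomeTPM(tx, occ, nSpikes = 20,
                             fractionScales = c(Total = 1, Free = 10,
                                                Bound = 0.1),
                             seed = 2)
  tm <- translationMetrics(tpm)
  err <- abs(tm$occupancy - occ[match(tm$gene_id, tx$gene_id)])
  expect_lt(median(err, na.rm = TRUE), 0.05)
  ## normalized bound+free recovers relative abundance (TPM is a
  ## per-kilobase rate, so multiply back by length before comparing);
  ## run at low count noise so the check exercises the normalization
  ## algebra rather than the NB noise floor
  tpm <- simulatePolysomeTPM(tx, occ, nSpikes = 20, phi = 1e4,
                             meanCount = 20000,
                             fractionScales = c(Total = 1, Free = 10,
                                                Bound = 0.1),
                             seed = 5)
  norm <- normalizeToSpikein(tpm)
  truth <- attr(tpm, "truth")
  tot <- with(norm[!norm$is_spike & norm$fraction == "Bound", ],
              setNames(norm_abundance, gene_id)) +
    with(norm[!norm$is_spike & norm$fraction == "Free", ],
         setNames(norm_abundance, gene_id))
  tot <- tot[truth$gene_id] * tx$length_total[match(truth$gene_id,
                                                    tx$gene_id)] / 1000
  ratio <- tot / truth$abundance
  relErr <- abs(ratio / median(ratio) - 1)
  expect_lt(median(relErr), 0.03)
})

test_that("depth scaling cancels exactly in the occupancy pipeline", {
  tx <- simulateTranscriptome(100, seed = 3)
  set.seed(42)
  occ <- runif(100)
  tpm <- simulatePolysomeTPM(tx, occ, seed = 4)
  tm0 <- translationMetrics(tpm)
  scaled <- tpm
  for (f in c("Total", "Free", "Bound")) {
    k <- c(Total = 3, Free = 0.2, Bound = 11)[[f]]
    scaled$tpm[scaled$fraction == f] <- scaled$tpm[scaled$fraction == f] * k
  }
  tm1 <- translationMetrics(scaled)
  expect_equal(tm1$occupancy, tm0$occupancy, tolerance = 1e-12)
})
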