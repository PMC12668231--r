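#' Simulate a transcriptome annotation table
#'
#' Draws transcript lengths (CDS + UTRs) from a log-normal distribution,
#' truncated to the realistic mRNA range \[100, 20000\] nt, and flags a
#' fixed fraction of genes as stress-induced. Induced genes are assigned to
#' the Hsf1 or Msn2/4 regulon alternately; all others carry regulon
#' `"none"`. UTR lengths are drawn log-normally around typical yeast
#' medians and capped so that the CDS keeps at least one codon.
#'
#' @param nGenes number of transcripts to simulate (>= 1).
#' @param lengthLogMean,lengthLogSd log-scale mean and SD of total
#'   transcript length; defaults give a median of 1500 nt.
#' @param fracInduced fraction of genes flagged stress-induced, in \[0, 1\];
#'   exactly `floor(fracInduced * nGenes)` genes are flagged.
#' @param seed integer seed; the same seed reproduces the same table.
#'
#' @return data.frame with columns `gene_id`, `length_total`, `utr5_len`,
#'   `utr3_len`, `regulon`, `induced`.
#' @examples
#' txome <- simulateTranscriptome(1000, fracInduced = 0.05, seed = 1)
#' sum(txome$induced)  # 50
#' @export
simulateTranscriptome <- function(nGenes, lengthLogMean = log(1500),
                                  lengthLogSd = 0.5, fracInduced = 0.05,
                                  seed = NULL) {
  stopifnotScalar(nGenes, "nGenes", positive = TRUE)
  if (nGenes < 1) stop("'nGenes' must be >= 1")
  nGenes <- as.integer(nGenes)
  if (fracInduced < 0 || fracInduced > 1) {
    stop("'fracInduced' must be in [0, 1]")
  }
  withSeed(seed, {
    len <- rlnorm(nGenes, lengthLogMean, lengthLogSd)
    len <- as.integer(round(pmin(pmax(len, 100), 20000)))
    utr5 <- as.integer(round(rlnorm(nGenes, log(68), 0.6)))
    utr3 <- as.integer(round(rlnorm(nGenes, log(91), 0.6)))
    ## keep length_total >= utr5 + utr3 + 3 (one codon of CDS)
    over <- utr5 + utr3 + 3L > len
    if (any(over)) {
      scale <- (len[over] - 3L) / (utr5[over] + utr3[over] + 1L)
      utr5[over] <- pmax(0L, as.integer(floor(utr5[over] * scale)))
      utr3[over] <- pmax(0L, as.integer(floor(utr3[over] * scale)))
    }
    nInd <- as.integer(floor(fracInduced * nGenes))
    induced <- rep(FALSE, nGenes)
    if (nInd > 0) induced[sample.int(nGenes, nInd)] <- TRUE
    regulon <- rep("none", nGenes)
    if (nInd > 0) {
      regulon[induced] <- rep_len(c("Hsf1", "Msn2/4"), nInd)
    }
    data.frame(
      gene_id = sprintf("g%05d", seq_len(nGenes)),
      length_total = len, utr5_len = utr5, utr3_len = utr3,
      regulon = regulon, induced = induced,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate true per-transcript pSup from the biophysical length model
#'
#' The noiseless surface is `pSup(L) = 1 - beta * L^x * exp(sign*(mu + nu*L))`,
#' i.e. the sedimented fraction grows as a power law of transcript length,
#' multiplied under stress by a per-transcript (`mu`) and per-nucleotide
#' (`nu`) condensation term. The surface is clipped into \[0.001, 0.999\],
#' jittered gene-by-gene on the log-odds scale with SD `sigmaG`, and
#' induced genes receive an additional log-odds escape offset `deltaE`.
#'
#' @param annotation transcriptome table from [simulateTranscriptome()]
#'   (needs `gene_id`, `length_total`, `induced`).
#' @param beta,x baseline power-law parameters; both must be positive.
#' @param mu,nu stress condensation terms (per transcript / per nucleotide).
#' @param sigmaG SD of gene-level log-odds jitter (>= 0).
#' @param deltaE log-odds escape offset added to induced genes.
#' @param exponentSign +1 (default) applies `exp(+(mu + nu*L))` to the
#'   sedimented fraction so that positive mu, nu mean more condensation;
#'   -1 flips the convention.
#' @param jitter optional per-gene log-odds jitter vector. The jitter
#'   models stable gene-specific sedimentation propensity, so when
#'   simulating several conditions of one study the same vector should be
#'   supplied to each (as [simulateSedSeqExperiment()] does); `NULL`
#'   draws `Normal(0, sigmaG)` internally.
#' @param seed integer seed.
#'
#' @return data.frame `gene_id`, `true_psup`, `true_lopsup`, plus the
#'   noiseless `model_psup`.
#' @examples
#' txome <- simulateTranscriptome(5, seed = 1)
#' txome$length_total <- rep(500L, 5)
#' simulateTruePSup(txome, beta = 1e-3, x = 1, sigmaG = 0)$true_psup # all 0.5
#' @export
simulateTruePSup <- function(annotation, beta = 1e-4, x = 1, mu = 0, nu = 0,
                             sigmaG = 0.3, deltaE = 0, exponentSign = 1,
                             jitter = NULL, seed = NULL) {
  stopifnotScalar(beta, "beta", positive = TRUE)
  stopifnotScalar(x, "x", positive = TRUE)
  if (sigmaG < 0) stop("'sigmaG' must be >= 0")
  if (!exponentSign %in% c(-1, 1)) stop("'exponentSign' must be +1 or -1")
  L <- annotation$length_total
  sed <- beta * L^x * exp(exponentSign * (mu + nu * L))
  nClip <- sum(sed > 1)
  if (nClip > length(L) / 2) {
    warning(sprintf(
      "sedimented fraction exceeds 1 for %d of %d genes before clipping",
      nClip, length(L)))
  }
  p0 <- pmin(pmax(1 - sed, 0.001), 0.999)
  withSeed(seed, {
    if (is.null(jitter)) jitter <- rnorm(length(L), 0, sigmaG)
    stopifnot(length(jitter) == length(L))
    lop <- logOdds(p0, eps = 0) + jitter
    if (!is.null(annotation$induced)) {
      lop <- lop + deltaE * as.numeric(annotation$induced)
    }
    p <- pmin(pmax(expit(lop), 0.001), 0.999)
    data.frame(gene_id = annotation$gene_id, true_psup = p,
               true_lopsup = logOdds(p, eps = 0), model_psup = p0,
               stringsAsFactors = FALSE)
  })
}

#' Simulate Sed-seq fraction counts with negative-binomial noise
#'
#' Generates Total/Sup/Pellet counts for one fractionation experiment from
#' true per-gene abundances and pSup values. Expected counts are
#' `E[T] = sT * alpha * c`, `E[S] = sS * alpha * p * c` and
#' `E[P] = sP * alpha * (1 - p) * c`, where the per-fraction depth factors
#' `sT, sS, sP` emulate differential processing of the fractions and `c`
#' scales mean total counts to `meanTotalCount`. Each count is drawn from a
#' negative binomial with that mean and size `phi`
#' (variance = m + m^2/phi). Conservation of mass holds in expectation with
#' implied mixing ratios `aS = sT/sS`, `aP = sT/sP`.
#'
#' @param annotation transcriptome table ([simulateTranscriptome()]).
#' @param truth data.frame with `true_psup` ([simulateTruePSup()]).
#' @param meanTotalCount target mean Total-fraction count per gene.
#' @param depthFactors named numeric `c(T=, S=, P=)` of positive
#'   per-fraction depth factors.
#' @param phi NB size (dispersion); must be positive.
#' @param abundance optional per-gene abundances; drawn log-normally
#'   (`abundanceLogSd`) when `NULL`.
#' @param abundanceLogSd log-scale SD of simulated abundances.
#' @param inductionLog2fc log2 fold-change applied to the abundance of
#'   induced genes (stress induction); 0 disables.
#' @param seed integer seed.
#'
#' @return list with `counts` (list of integer vectors `Total`, `Sup`,
#'   `Pellet`), `aS`, `aP` (true mixing ratios implied by the depth
#'   factors), `abundance`, and `expected` (list of expected counts).
#' @examples
#' txome <- simulateTranscriptome(200, seed = 1)
#' truth <- simulateTruePSup(txome, seed = 2)
#' sim <- simulateSedSeqCounts(txome, truth, meanTotalCount = 500, seed = 3)
#' c(sim$aS, sim$aP)
#' @export
simulateSedSeqCounts <- function(annotation, truth, meanTotalCount = 1000,
                                 depthFactors = c(T = 1, S = 1, P = 1),
                                 phi = 50, abundance = NULL,
                                 abundanceLogSd = 1, inductionLog2fc = 0,
                                 seed = NULL) {
  stopifnotScalar(phi, "phi", positive = TRUE)
  stopifnotScalar(meanTotalCount, "meanTotalCount", positive = TRUE)
  if (any(depthFactors <= 0)) stop("depth factors must be positive")
  sT <- depthFactors[["T"]]; sS <- depthFactors[["S"]]; sP <- depthFactors[["P"]]
  n <- nrow(annotation)
  p <- truth$true_psup
  stopifnot(length(p) == n)
  withSeed(seed, {
    if (is.null(abundance)) {
      abundance <- rlnorm(n, 0, abundanceLogSd)
    }
    if (inductionLog2fc != 0 && !is.null(annotation$induced)) {
      abundance <- abundance * 2^(inductionLog2fc * as.numeric(annotation$induced))
    }
    cc <- meanTotalCount / (sT * mean(abundance))
    mT <- sT * abundance * cc
    mS <- sS * abundance * p * cc
    mP <- sP * abundance * (1 - p) * cc
    counts <- list(
      Total  = rnbinom(n, mu = mT, size = phi),
      Sup    = rnbinom(n, mu = mS, size = phi),
      Pellet = rnbinom(n, mu = mP, size = phi)
    )
    counts <- lapply(counts, function(v) setNames(as.integer(v),
                                                  annotation$gene_id))
    list(counts = counts, aS = sT / sS, aP = sT / sP,
         abundance = abundance,
         expected = list(Total = mT, Sup = mS, Pellet = mP))
  })
}

#' Simulate a multi-condition Sed-seq experiment with known truth
#'
#' Convenience wrapper producing a ready-to-analyse [SedSeqExperiment-class]:
#' a mock (baseline) condition plus an optional stress condition whose true
#' pSup surface carries the condensation terms `mu`, `nu`, whose induced
#' genes escape by `deltaE` log-odds, and whose induced-gene abundances are
#' multiplied by `2^inductionLog2fc`. All ground truth (per-gene true pSup
#' per condition, mixing ratios, abundances, parameters) is stored in
#' `metadata(se)$truth`.
#'
#' @param nGenes number of genes.
#' @param replicates replicates per condition.
#' @param conditions character vector; first entry is the control.
#' @param beta,x,sigmaG baseline surface parameters (see
#'   [simulateTruePSup()]).
#' @param mu,nu,deltaE,inductionLog2fc stress parameters, applied to every
#'   non-control condition.
#' @param fracInduced fraction of induced genes.
#' @param meanTotalCount,phi count model parameters
#'   (see [simulateSedSeqCounts()]).
#' @param depthFactors per-fraction depth factors, either a single named
#'   vector used for every experiment or a list (one per experiment column).
#' @param exponentSign stress exponent convention.
#' @param seed master seed; every internal draw derives its own stream.
#'
#' @return A [SedSeqExperiment-class]; `metadata(x)$truth` holds the
#'   ground-truth tables.
#' @examples
#' se <- simulateSedSeqExperiment(nGenes = 300, seed = 1)
#' se
#' @export
simulateSedSeqExperiment <- function(nGenes = 2000, replicates = 2,
                                     conditions = c("mock", "stress"),
                                     beta = 1e-4, x = 1, sigmaG = 0.3,
                                     mu = log(2), nu = 2e-4, deltaE = 1,
                                     inductionLog2fc = 2, fracInduced = 0.05,
                                     meanTotalCount = 1000, phi = 50,
                                     depthFactors = c(T = 1, S = 1, P = 1),
                                     exponentSign = 1, seed = NULL) {
  txome <- simulateTranscriptome(nGenes, fracInduced = fracInduced,
                                 seed = childSeed(seed, 1))
  nExp <- length(conditions) * replicates
  if (!is.list(depthFactors)) {
    depthFactors <- rep(list(depthFactors), nExp)
  }
  stopifnot(length(depthFactors) == nExp)

  truthTabs <- list()
  mats <- list(Total = NULL, Sup = NULL, Pellet = NULL)
  cond <- character(); repl <- integer(); mixing <- list()
  ## gene-level jitter is a stable property of each transcript (sequence,
  ## intrinsic propensity), so one draw is shared by every condition
  jitter <- withSeed(childSeed(seed, 99), rnorm(nGenes, 0, sigmaG))
  k <- 0L
  for (cd in conditions) {
    stressed <- cd != conditions[[1]]
    truth <- simulateTruePSup(
      txome, beta = beta, x = x,
      mu = if (stressed) mu else 0, nu = if (stressed) nu else 0,
      sigmaG = sigmaG, deltaE = if (stressed) deltaE else 0,
      exponentSign = exponentSign, jitter = jitter,
      seed = childSeed(seed, 100 + k)
    )
    truthTabs[[cd]] <- truth
    for (r in seq_len(replicates)) {
      k <- k + 1L
      sim <- simulateSedSeqCounts(
        txome, truth, meanTotalCount = meanTotalCount,
        depthFactors = depthFactors[[k]], phi = phi,
        inductionLog2fc = if (stressed) inductionLog2fc else 0,
        seed = childSeed(seed, 200 + k)
      )
      for (a in names(mats)) mats[[a]] <- cbind(mats[[a]], sim$counts[[a]])
      cond <- c(cond, cd); repl <- c(repl, r)
      mixing[[k]] <- c(aS = sim$aS, aP = sim$aP)
    }
  }
  sampleNames <- paste(cond, repl, sep = "_")
  for (a in names(mats)) colnames(mats[[a]]) <- sampleNames
  truthMeta <- list(
    psup = truthTabs, mixing = setNames(mixing, sampleNames),
    params = list(beta = beta, x = x, mu = mu, nu = nu, sigmaG = sigmaG,
                  deltaE = deltaE, inductionLog2fc = inductionLog2fc,
                  phi = phi, exponentSign = exponentSign,
                  meanTotalCount = meanTotalCount, seed = seed)
  )
  SedSeqExperiment(mats$Total, mats$Sup, mats$Pellet,
                   condition = cond, replicate = repl, rowData = txome,
                   metadata = list(truth = truthMeta))
}

#' Simulate polysome-fraction TPM tables with spike-ins
#'
#' Emulates spike-in-anchored polysome sequencing: each transcript's
#' abundance splits into a ribosome-bound part (`abundance * occupancy`)
#' and a free part, each fraction is scaled by an arbitrary per-fraction
#' depth factor (emulating independent library depths), counts are drawn
#' with NB noise and converted to TPM. Spike-in transcripts share one true
#' abundance across all fractions, which is what makes absolute occupancy
#' recoverable downstream.
#'
#' @param annotation transcriptome table; lengths are used for TPM.
#' @param occupancy per-gene true ribosome occupancy in \[0, 1\].
#' @param nSpikes number of spike-in transcripts (>= 1).
#' @param spikeAbundance common true abundance of each spike-in, on the
#'   same arbitrary scale as `abundance`.
#' @param fractionScales named numeric `c(Total=, Free=, Bound=)` depth
#'   factors.
#' @param phi NB size for count noise.
#' @param meanCount target mean per-gene count in the Total fraction.
#' @param abundance optional true abundances (log-normal if `NULL`).
#' @param abundanceLogSd log-scale SD for drawn abundances.
#' @param seed integer seed.
#'
#' @return data.frame in long format: `gene_id`, `fraction`
#'   (Total/Free/Bound), `tpm`, `est_counts`, `is_spike`, plus a
#'   `truth` attribute with per-gene true occupancy and abundance.
#' @examples
#' txome <- simulateTranscriptome(100, seed = 1)
#' tpm <- simulatePolysomeTPM(txome, occupancy = runif(100), seed = 2)
#' head(tpm)
#' @export
simulatePolysomeTPM <- function(annotation, occupancy, nSpikes = 20,
                                spikeAbundance = 5,
                                fractionScales = c(Total = 1, Free = 1, Bound = 1),
                                phi = 100, meanCount = 500,
                                abundance = NULL, abundanceLogSd = 1,
                                seed = NULL) {
  if (nSpikes < 1) stop("'nSpikes' must be >= 1")
  if (any(occupancy < 0 | occupancy > 1)) {
    stop("'occupancy' values must lie in [0, 1]")
  }
  n <- nrow(annotation)
  stopifnot(length(occupancy) == n)
  withSeed(seed, {
    if (is.null(abundance)) abundance <- rlnorm(n, 0, abundanceLogSd)
    spikeIds <- sprintf("spike%03d", seq_len(nSpikes))
    spikeLen <- rep(1000L, nSpikes)
    ids <- c(annotation$gene_id, spikeIds)
    len <- c(annotation$length_total, spikeLen)
    isSpike <- c(rep(FALSE, n), rep(TRUE, nSpikes))
    ## true per-fraction abundances; spikes identical in every fraction
    ab <- list(
      Total = c(abundance, rep(spikeAbundance, nSpikes)),
      Free  = c(abundance * (1 - occupancy), rep(spikeAbundance, nSpikes)),
      Bound = c(abundance * occupancy, rep(spikeAbundance, nSpikes))
    )
    cc <- meanCount / mean(ab$Total)
    out <- lapply(names(ab), function(f) {
      m <- ab[[f]] * fractionScales[[f]] * cc
      cnt <- rnbinom(length(m), mu = m, size = phi)
      rate <- cnt / (len / 1000)
      tpm <- rate / sum(rate) * 1e6
      data.frame(gene_id = ids, fraction = f, tpm = tpm,
                 est_counts = as.integer(cnt), is_spike = isSpike,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "truth") <- data.frame(
      gene_id = annotation$gene_id, occupancy = occupancy,
      abundance = abundance, stringsAsFactors = FALSE)
    res
  })
}
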