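#' Windowed length profile of log-odds pSup
#'
#' For each gene with log-length l, computes the mean (`mu`) and SD
#' (`sigma`) of log-odds pSup over all genes whose log-length falls inside
#' a window centred on l. The window width is `windowFraction` of the full
#' log-length range of the transcriptome (default 0.02), truncated at the
#' data range. The global residual SD `sigmaControl` is the SD over all
#' genes of `lopsup - mu`; when the profile is built on a control
#' condition this is the sigma(control) used to standardize the
#' condensation scores.
#'
#' @param lop numeric vector of log-odds pSup values (one per gene).
#' @param length transcript lengths in nt (same order).
#' @param windowFraction window width as a fraction of the log-length
#'   range, in (0, 1\].
#'
#' @return list of class `lengthProfile`: per-gene `mu`, `sigma`
#'   (NA where the window holds only the focal gene, counted in
#'   `nUndefinedSigma`), `sigmaControl`, `windowFraction`, `window`
#'   (width in log units).
#' @examples
#' lp <- lengthProfile(rnorm(100), exp(runif(100, 5, 9)))
#' lp$sigmaControl
#' @export
lengthProfile <- function(lop, length, windowFraction = 0.02) {
  if (windowFraction <= 0 || windowFraction > 1) {
    stop("'windowFraction' must be in (0, 1]")
  }
  stopifnot(base::length(lop) == base::length(length))
  n <- base::length(lop)
  ok <- !is.na(lop) & !is.na(length) & length > 0
  if (sum(ok) < 2 || base::length(unique(length[ok])) < 2) {
    stop("need at least 2 genes with distinct lengths")
  }
  logL <- log(length)
  rng <- range(logL[ok])
  w <- windowFraction * diff(rng)

  ord <- order(logL)
  okS <- ok[ord]
  lS <- logL[ord]
  vS <- lop[ord]
  ## cumulative sums over the usable genes in length order
  use <- which(okS)
  lu <- lS[use]; vu <- vS[use]
  cs <- cumsum(vu); cs2 <- cumsum(vu^2)
  mu <- sig <- rep(NA_real_, n)
  ## window membership via binary search on the sorted usable lengths
  lo <- findInterval(lS - w / 2, lu, left.open = TRUE) + 1L
  hi <- findInterval(lS + w / 2, lu)
  for (i in seq_len(n)) {
    if (!okS[i]) next
    a <- lo[i]; b <- hi[i]
    m <- b - a + 1L
    if (m < 1L) next
    s1 <- cs[b] - if (a > 1L) cs[a - 1L] else 0
    mu[ord[i]] <- s1 / m
    if (m >= 2L) {
      s2 <- cs2[b] - if (a > 1L) cs2[a - 1L] else 0
      v <- (s2 - s1^2 / m) / (m - 1L)
      sig[ord[i]] <- sqrt(max(v, 0))
    }
  }
  nUndef <- sum(ok & is.na(sig))
  if (nUndef > 0) {
    warning(sprintf("sigma undefined for %d gene(s) whose window contains only the focal gene", nUndef))
  }
  resid <- lop - mu
  structure(list(mu = mu, sigma = sig,
                 sigmaControl = sd(resid[ok & !is.na(mu)]),
                 windowFraction = windowFraction, window = w,
                 nUndefinedSigma = nUndef),
            class = "lengthProfile")
}

#' Differential sedimentation score (delta-Sed)
#'
#' Standardized treatment-induced change in sedimentation per transcript:
#' `deltaSed = (lopsup_control - lopsup_treatment) / sigmaControl`,
#' where `sigmaControl` is the control condition's global residual SD
#' around its length profile. Positive values mean the transcript
#' sediments more (condenses) under treatment; the control scored against
#' itself is exactly 0.
#'
#' @param lopControl,lopTreatment per-gene log-odds pSup in the control
#'   and treatment conditions (same gene order).
#' @param profileControl a [lengthProfile()] built on the control, or a
#'   numeric `sigmaControl` value. With `sigmaMode = "windowed"` the
#'   per-gene windowed SD of the control profile is used as the
#'   denominator instead of the global value.
#' @param sigmaMode `"global"` (default) or `"windowed"`.
#'
#' @return numeric vector of delta-Sed values (sigma units).
#' @examples
#' deltaSed(1, -1, 0.5)  # 4
#' @export
deltaSed <- function(lopControl, lopTreatment, profileControl,
                     sigmaMode = c("global", "windowed")) {
  sigmaMode <- match.arg(sigmaMode)
  denom <- scoreDenominator(profileControl, sigmaMode)
  (lopControl - lopTreatment) / denom
}

#' Escape score (eSed)
#'
#' A transcript's treatment-induced sedimentation change relative to
#' transcripts of similar length:
#' `eSed = ((lop_T - mu(L,T)) - (lop_C - mu(L,C))) / sigmaControl`.
#' Positive eSed means the transcript sediments less than its length
#' cohort under treatment (escapes condensation).
#'
#' @param lopControl,lopTreatment per-gene log-odds pSup.
#' @param profileControl,profileTreatment [lengthProfile()] objects for
#'   the two conditions, built with the same window fraction.
#' @param sigmaMode `"global"` (default) or `"windowed"` (denominator from
#'   the control profile's per-gene windowed SD).
#'
#' @return numeric vector of eSed values (sigma units).
#' @export
escapeSed <- function(lopControl, lopTreatment, profileControl,
                      profileTreatment, sigmaMode = c("global", "windowed")) {
  sigmaMode <- match.arg(sigmaMode)
  if (!isTRUE(all.equal(profileControl$windowFraction,
                        profileTreatment$windowFraction))) {
    stop("profiles must be computed with the same window fraction")
  }
  denom <- scoreDenominator(profileControl, sigmaMode)
  ((lopTreatment - profileTreatment$mu) -
     (lopControl - profileControl$mu)) / denom
}

scoreDenominator <- function(profileControl, sigmaMode) {
  if (is.numeric(profileControl) && !is.list(profileControl)) {
    denom <- profileControl
  } else if (sigmaMode == "windowed") {
    denom <- profileControl$sigma
  } else {
    denom <- profileControl$sigmaControl
  }
  if (all(is.na(denom)) || isTRUE(all(denom == 0))) {
    stop("degenerate control: sigma(control) is zero or undefined")
  }
  if (any(!is.na(denom) & denom == 0)) denom[denom == 0] <- NA_real_
  denom
}

#' Length-binned sedimentation Z-score (sedScore / rSed)
#'
#' Within each replicate, transcripts are sorted by length (UTRs
#' included), partitioned into consecutive bins of `binSize` (a final
#' partial bin is merged into the preceding one so the longest transcripts
#' are never discarded), and each transcript's log-odds pSup is Z-scored
#' against its bin. The reported score is the mean of the per-replicate
#' Z-scores. Ties in length are broken by gene identifier so binning is
#' deterministic.
#'
#' The default orientation is sedimentation-positive: a transcript that
#' sediments more than its length cohort (lower log-odds pSup) gets a
#' positive rSed, matching the interpretation of "relative sedimentation".
#'
#' @param lop matrix of log-odds pSup, genes x replicates (a vector is
#'   treated as one replicate).
#' @param length transcript lengths in nt.
#' @param geneId gene identifiers used for tie-breaking (defaults to
#'   rownames of `lop` or the index).
#' @param binSize transcripts per length bin (default 100).
#' @param orientation `"sedimentation"` (default; positive = sediments
#'   more) or `"supernatant"` (positive = more soluble, the raw Z of
#'   log-odds pSup).
#'
#' @return numeric vector of sedScores, one per gene, in the input order.
#'   Bins with zero within-bin SD yield `NA` with a warning.
#' @export
sedScore <- function(lop, length, geneId = NULL, binSize = 100,
                     orientation = c("sedimentation", "supernatant")) {
  orientation <- match.arg(orientation)
  lop <- as.matrix(lop)
  n <- nrow(lop)
  stopifnot(base::length(length) == n)
  if (n < binSize) stop("need at least 'binSize' genes")
  if (is.null(geneId)) {
    geneId <- rownames(lop)
    if (is.null(geneId)) geneId <- sprintf("%09d", seq_len(n))
  }
  ord <- order(length, geneId)
  nBins <- max(1L, n %/% binSize)
  ## consecutive bins of binSize; trailing partial bin merged into the last
  bin <- pmin((seq_len(n) - 1L) %/% binSize + 1L, nBins)
  binOfGene <- integer(n)
  binOfGene[ord] <- bin

  zsum <- rep(0, n); znum <- rep(0L, n)
  degenerate <- FALSE
  for (r in seq_len(ncol(lop))) {
    v <- lop[, r]
    for (b in seq_len(nBins)) {
      idx <- which(binOfGene == b)
      vb <- v[idx]
      okb <- !is.na(vb)
      if (sum(okb) < 2) next
      m <- mean(vb[okb]); s <- sd(vb[okb])
      if (is.na(s) || s == 0) { degenerate <- TRUE; next }
      z <- (vb - m) / s
      zsum[idx] <- zsum[idx] + ifelse(is.na(z), 0, z)
      znum[idx] <- znum[idx] + as.integer(!is.na(z))
    }
  }
  if (degenerate) {
    warning("one or more length bins had zero within-bin SD; their genes are NA for that replicate")
  }
  out <- ifelse(znum > 0, zsum / znum, NA_real_)
  if (orientation == "sedimentation") out <- -out
  names(out) <- geneId
  out
}

#' Condensation score table for a control/treatment pair
#'
#' High-level wrapper computing delta-Sed, eSed and the sedScore (rSed)
#' for every gene of a [SedSeqExperiment-class] processed by
#' [computePSup()]. Per-replicate log-odds pSup values are averaged within
#' condition before delta-Sed/eSed (the sedScore instead averages
#' per-replicate Z-scores, its defining replicate rule);
#' `combineReplicates = "scores"` switches delta-Sed/eSed to averaging
#' per-replicate scores instead.
#'
#' @param object a `SedSeqExperiment` with `lopsup` assay.
#' @param control,treatment condition labels present in
#'   `colData(object)$condition`.
#' @param windowFraction window for the length profiles (default 0.02).
#' @param binSize sedScore bin size (default 100).
#' @param sigmaMode denominator convention, `"global"` or `"windowed"`.
#' @param combineReplicates `"lopsup"` (default: average log-odds across
#'   replicates, then score) or `"scores"` (score each replicate pair,
#'   then average).
#'
#' @return `DataFrame` with `gene_id`, `condition`, `delta_sed`, `e_sed`,
#'   `r_sed`, plus the profile quantities `mu_control`, `mu_treatment`,
#'   `sigma_window_control`; `metadata()` carries `sigmaControl`.
#' @examples
#' se <- simulateSedSeqExperiment(nGenes = 400, seed = 1)
#' se <- computePSup(se, estimateMixingRatios(se))
#' sc <- condensationScores(se, "mock", "stress")
#' head(sc)
#' @export
condensationScores <- function(object, control, treatment,
                               windowFraction = 0.02, binSize = 100,
                               sigmaMode = c("global", "windowed"),
                               combineReplicates = c("lopsup", "scores")) {
  sigmaMode <- match.arg(sigmaMode)
  combineReplicates <- match.arg(combineReplicates)
  cond <- colData(object)$condition
  if (!control %in% cond) stop("control condition not found: ", control)
  if (!treatment %in% cond) stop("treatment condition not found: ", treatment)
  lom <- lopsup(object)
  len <- rowData(object)$length_total
  ctlCols <- which(cond == control)
  trtCols <- which(cond == treatment)
  avg <- function(cols) rowMeans(lom[, cols, drop = FALSE], na.rm = TRUE)

  lopC <- avg(ctlCols); lopT <- avg(trtCols)
  lopC[is.nan(lopC)] <- NA; lopT[is.nan(lopT)] <- NA
  profC <- suppressWarnings(lengthProfile(lopC, len, windowFraction))
  profT <- suppressWarnings(lengthProfile(lopT, len, windowFraction))

  if (combineReplicates == "lopsup") {
    dsed <- deltaSed(lopC, lopT, profC, sigmaMode)
    esed <- escapeSed(lopC, lopT, profC, profT, sigmaMode)
  } else {
    pairScore <- function(fun) {
      mats <- sapply(seq_along(trtCols), function(k) {
        jC <- ctlCols[min(k, base::length(ctlCols))]
        jT <- trtCols[k]
        pc <- suppressWarnings(lengthProfile(lom[, jC], len, windowFraction))
        pt <- suppressWarnings(lengthProfile(lom[, jT], len, windowFraction))
        if (identical(fun, "delta")) {
          deltaSed(lom[, jC], lom[, jT], pc, sigmaMode)
        } else {
          escapeSed(lom[, jC], lom[, jT], pc, pt, sigmaMode)
        }
      })
      rowMeans(as.matrix(mats), na.rm = TRUE)
    }
    dsed <- pairScore("delta")
    esed <- pairScore("escape")
  }
  rsed <- suppressWarnings(
    sedScore(lom[, trtCols, drop = FALSE], len,
             geneId = rownames(object), binSize = binSize))
  out <- DataFrame(
    gene_id = rownames(object), condition = treatment,
    delta_sed = unname(dsed), e_sed = unname(esed), r_sed = unname(rsed),
    mu_control = profC$mu, mu_treatment = profT$mu,
    sigma_window_control = profC$sigma)
  metadata(out) <- list(sigmaControl = profC$sigmaControl,
                        windowFraction = windowFraction, binSize = binSize,
                        sigmaMode = sigmaMode,
                        combineReplicates = combineReplicates)
  out
}
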