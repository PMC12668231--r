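#' Normalize polysome-fraction abundances to the spike-in median
#'
#' Each fraction of a spike-in-anchored polysome experiment is sequenced
#' to an arbitrary depth; dividing every transcript's abundance by the
#' median abundance of that fraction's qualifying spike-in transcripts
#' puts all fractions on a common absolute scale. A spike-in qualifies in
#' a fraction when its estimated counts exceed `minSpikeCounts`.
#'
#' @param tpm long-format data.frame with columns `gene_id`, `fraction`,
#'   `tpm`, `est_counts`, `is_spike` (as written by
#'   [simulatePolysomeTPM()] or read with [readTpmTable()]).
#' @param minSpikeCounts spike-in count threshold (default 100).
#'
#' @return the input with an added `norm_abundance` column
#'   (= tpm / median spike tpm of the fraction).
#' @export
normalizeToSpikein <- function(tpm, minSpikeCounts = 100) {
  need <- c("gene_id", "fraction", "tpm", "est_counts", "is_spike")
  if (!all(need %in% names(tpm))) {
    stop("tpm table must have columns: ", paste(need, collapse = ", "))
  }
  out <- tpm
  out$norm_abundance <- NA_real_
  for (f in unique(tpm$fraction)) {
    inF <- tpm$fraction == f
    sp <- inF & tpm$is_spike & tpm$est_counts > minSpikeCounts
    if (!any(sp)) {
      stop(sprintf(
        "no spike-in transcript with more than %d estimated counts in fraction '%s'",
        minSpikeCounts, f))
    }
    out$norm_abundance[inF] <- tpm$tpm[inF] / median(tpm$tpm[sp])
  }
  out
}

#' Ribosome occupancy from spike-normalized bound and free abundances
#'
#' The fraction of a transcript's molecules bound by at least one
#' ribosome: `occupancy = bound / (bound + free)`, computed from
#' spike-in-normalized abundances so that per-fraction sequencing depth
#' cancels exactly. Genes absent from both fractions yield `NA`.
#'
#' @param bound,free spike-normalized abundances (same gene order), e.g.
#'   the `norm_abundance` column of [normalizeToSpikein()] split by
#'   fraction.
#'
#' @return numeric vector of occupancies in \[0, 1\].
#' @examples
#' ribosomeOccupancy(c(1, 3, 0), c(1, 1, 0))  # 0.5, 0.75, NA
#' @export
ribosomeOccupancy <- function(bound, free) {
  if (any(c(bound, free) < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative")
  }
  den <- bound + free
  ifelse(!is.na(den) & den > 0, bound / den, NA_real_)
}

#' Ribosome association score
#'
#' `association = TPM_bound / TPM_total` — a relative translation measure
#' usable for stressed samples where condensed RNA may pellet out of the
#' gradient, making absolute occupancy incalculable. Unlike occupancy it
#' is not bounded by 1 (composition effects).
#'
#' @param tpmBound,tpmTotal TPM of each gene in the ribosome-bound and
#'   total fractions.
#'
#' @return numeric vector; `NA` where total TPM is 0.
#' @export
ribosomeAssociation <- function(tpmBound, tpmTotal) {
  if (any(c(tpmBound, tpmTotal) < 0, na.rm = TRUE)) {
    stop("TPM values must be non-negative")
  }
  ifelse(!is.na(tpmTotal) & tpmTotal > 0, tpmBound / tpmTotal, NA_real_)
}

#' Ribosome occupancy from a sucrose-cushion assay with EDTA correction
#'
#' In the cushion assay, the pelleted share of a transcript measured
#' without EDTA mixes ribosome-bound material with EDTA-insensitive
#' condensates; the share still pelleting with EDTA (which dissociates
#' polysomes) estimates the condensate background. The default corrected
#' occupancy is the floored difference
#' `max(pSed(-EDTA) - pSed(+EDTA), 0)`; with `renormalize = TRUE` the
#' difference is rescaled by the non-condensed pool,
#' `(pSed(-EDTA) - pSed(+EDTA)) / (1 - pSed(+EDTA))`.
#'
#' @param pSedMinusEdta,pSedPlusEdta pelleted fractions in \[0, 1\]
#'   measured without / with EDTA.
#' @param renormalize use the renormalized variant.
#'
#' @return list with `occupancy` and `nFloored` (how many transcripts
#'   pelleted more with EDTA and were floored at 0).
#' @examples
#' occupancyFromCushion(0.8, 0.1)$occupancy                      # 0.7
#' occupancyFromCushion(0.8, 0.1, renormalize = TRUE)$occupancy  # 0.778
#' @export
occupancyFromCushion <- function(pSedMinusEdta, pSedPlusEdta,
                                 renormalize = FALSE) {
  if (any(c(pSedMinusEdta, pSedPlusEdta) < 0, na.rm = TRUE) ||
      any(c(pSedMinusEdta, pSedPlusEdta) > 1, na.rm = TRUE)) {
    stop("pelleted fractions must lie in [0, 1]")
  }
  diffRaw <- pSedMinusEdta - pSedPlusEdta
  nFloored <- sum(diffRaw < 0, na.rm = TRUE)
  occ <- pmax(diffRaw, 0)
  if (renormalize) {
    if (any(pSedPlusEdta == 1, na.rm = TRUE)) {
      stop("pSed(+EDTA) = 1: renormalized occupancy undefined")
    }
    occ <- occ / (1 - pSedPlusEdta)
  }
  list(occupancy = occ, nFloored = nFloored)
}

#' Occupancy and association table from a polysome TPM table
#'
#' Convenience wrapper: spike-normalizes a long TPM table
#' (Total/Free/Bound fractions) and returns per-gene ribosome occupancy
#' and association.
#'
#' @param tpm long TPM table (see [normalizeToSpikein()]).
#' @param minSpikeCounts spike-in count threshold.
#'
#' @return data.frame `gene_id`, `occupancy`, `association` for
#'   non-spike genes.
#' @export
translationMetrics <- function(tpm, minSpikeCounts = 100) {
  norm <- normalizeToSpikein(tpm, minSpikeCounts)
  genes <- unique(norm$gene_id[!norm$is_spike])
  grab <- function(frac, col = "norm_abundance") {
    sub <- norm[norm$fraction == frac & !norm$is_spike, ]
    setNames(sub[[col]], sub$gene_id)[genes]
  }
  bound <- grab("Bound"); free <- grab("Free")
  tpmBound <- grab("Bound", "tpm"); tpmTotal <- grab("Total", "tpm")
  data.frame(
    gene_id = genes,
    occupancy = unname(ribosomeOccupancy(bound, free)),
    association = unname(ribosomeAssociation(tpmBound, tpmTotal)),
    stringsAsFactors = FALSE)
}
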