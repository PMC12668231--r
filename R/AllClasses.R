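#' SedSeqExperiment: fraction counts with transcript annotation
#'
#' A `SummarizedExperiment` subclass for Sed-seq data. Assays `"Total"`,
#' `"Sup"` and `"Pellet"` hold gene-by-sample count matrices for the three
#' fractions of each fractionation experiment; `colData` carries the
#' `condition` and `replicate` labels identifying each experiment; `rowData`
#' carries the transcript annotation (`length_total`, `utr5_len`,
#' `utr3_len`, `regulon`, `induced`). Assays `"psup"` and `"lopsup"` are
#' added by [computePSup()].
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [SedSeqExperiment()] constructor, [estimateMixingRatios()],
#'   [computePSup()]
#' @export
setClass("SedSeqExperiment", contains = "SummarizedExperiment")

setValidity("SedSeqExperiment", function(object) {
  msg <- character()
  need <- c("Total", "Sup", "Pellet")
  if (!all(need %in% assayNames(object))) {
    msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
  }
  for (a in intersect(need, assayNames(object))) {
    m <- assay(object, a)
    if (any(!is.na(m) & m < 0)) {
      msg <- c(msg, sprintf("assay '%s' contains negative counts", a))
    }
  }
  cd <- colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData must have 'condition' and 'replicate' columns")
  }
  rd <- rowData(object)
  if ("length_total" %in% colnames(rd)) {
    if (any(!is.na(rd$length_total) & rd$length_total <= 0)) {
      msg <- c(msg, "rowData$length_total must be positive")
    }
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "gene identifiers (rownames) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SedSeqExperiment
#'
#' @param total,sup,pellet gene-by-sample count matrices with identical
#'   dimensions and dimnames. Column order defines the experiments.
#' @param condition,replicate per-column experiment labels, recycled to the
#'   number of columns.
#' @param rowData optional `DataFrame`/data.frame of transcript annotation
#'   (one row per gene); typically from [simulateTranscriptome()] or
#'   [readAnnotation()].
#' @param metadata optional list stored in the object metadata (simulation
#'   truth, provenance, ...).
#'
#' @return A [SedSeqExperiment-class] object.
#' @examples
#' txome <- simulateTranscriptome(50, seed = 1)
#' truth <- simulateTruePSup(txome, seed = 2)
#' sim <- simulateSedSeqCounts(txome, truth, meanTotalCount = 200, seed = 3)
#' se <- SedSeqExperiment(sim$counts$Total, sim$counts$Sup, sim$counts$Pellet,
#'                        condition = "mock", replicate = 1L, rowData = txome)
#' se
#' @export
SedSeqExperiment <- function(total, sup, pellet,
                             condition = "control", replicate = 1L,
                             rowData = NULL, metadata = list()) {
  total <- as.matrix(total); sup <- as.matrix(sup); pellet <- as.matrix(pellet)
  if (!all(dim(total) == dim(sup)) || !all(dim(total) == dim(pellet))) {
    stop("total, sup and pellet must have identical dimensions")
  }
  nSamp <- ncol(total)
  condition <- rep_len(as.character(condition), nSamp)
  replicate <- rep_len(as.integer(replicate), nSamp)
  cd <- DataFrame(condition = condition, replicate = replicate)
  rownames(cd) <- colnames(total)
  if (is.null(rownames(cd))) {
    rownames(cd) <- paste(condition, replicate, sep = "_")
    colnames(total) <- colnames(sup) <- colnames(pellet) <- rownames(cd)
  }
  args <- list(
    assays = SimpleList(Total = total, Sup = sup, Pellet = pellet),
    colData = cd, metadata = metadata
  )
  if (!is.null(rowData)) {
    rowData <- DataFrame(rowData)
    if (!is.null(rowData$gene_id)) rownames(rowData) <- rowData$gene_id
    args$rowData <- rowData
  }
  se <- do.call(SummarizedExperiment, args)
  new("SedSeqExperiment", se)
}

#' MixingFit: per-experiment mixing-ratio estimates
#'
#' Result of [estimateMixingRatios()] for one fractionation experiment:
#' point estimates of the mixing ratios \eqn{a_S} and \eqn{a_P} relating
#' supernatant and pellet counts back to the total fraction under
#' conservation of mass, and of the negative-binomial dispersion.
#'
#' @slot aS,aP positive mixing-ratio estimates.
#' @slot phi positive NB size (dispersion) estimate; variance is
#'   \eqn{m + m^2/\phi}.
#' @slot nGenesUsed number of genes passing the count filter used for the fit.
#' @slot objective log-posterior value at the optimum.
#' @slot mode `"map"` or `"posterior"`.
#' @slot warnings character vector of diagnostics (e.g. identifiability).
#' @slot posterior list of posterior summaries (means, 95% intervals) in
#'   posterior mode; empty otherwise.
#' @seealso [estimateMixingRatios()], [computePSup()]
#' @export
setClass("MixingFit",
  representation(aS = "numeric", aP = "numeric", phi = "numeric",
                 nGenesUsed = "integer", objective = "numeric",
                 mode = "character", warnings = "character",
                 posterior = "list"))

setValidity("MixingFit", function(object) {
  msg <- character()
  if (length(object@aS) != 1L || object@aS <= 0) msg <- c(msg, "aS must be a single positive value")
  if (length(object@aP) != 1L || object@aP <= 0) msg <- c(msg, "aP must be a single positive value")
  if (length(object@phi) != 1L || object@phi <= 0) msg <- c(msg, "phi must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' @describeIn MixingFit-class mixing-ratio accessor, `c(aS, aP)`.
#' @param object a `MixingFit`.
#' @export
mixingRatios <- function(object) {
  stopifnot(is(object, "MixingFit"))
  c(aS = object@aS, aP = object@aP)
}

#' @describeIn MixingFit-class NB dispersion accessor.
#' @export
dispersion <- function(object) {
  stopifnot(is(object, "MixingFit"))
  object@phi
}

setMethod("show", "MixingFit", function(object) {
  cat(sprintf("MixingFit (%s): aS = %.4g, aP = %.4g, phi = %.4g\n",
              object@mode, object@aS, object@aP, object@phi))
  cat(sprintf("  genes used: %d  log-posterior: %.4g\n",
              object@nGenesUsed, object@objective))
  if (length(object@warnings)) {
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
  }
  invisible(NULL)
})

#' SedModelFit: fitted biophysical sedimentation model
#'
#' Result of [fitBaselineSedModel()] / [fitStressSedModel()]. The model
#' predicts the sedimented fraction of a transcript of length L as
#' \eqn{\beta L^x \exp(s(\mu + \nu L))} (s the exponent-sign convention),
#' so pSup = 1 - sedimented fraction, and is fit by least squares on the
#' log-odds pSup scale.
#'
#' @slot beta,x baseline parameters (length-power law of sedimentation).
#' @slot mu,nu stress condensation parameters: per-transcript (mu) and
#'   per-nucleotide (nu) terms; 0 for the baseline fit.
#' @slot exponentSign +1 or -1; grouping convention for the stress exponent.
#' @slot rss residual sum of squares on the log-odds scale.
#' @slot nObs number of observations used.
#' @slot nPar number of freely fitted parameters.
#' @slot free names of the freely fitted parameters.
#' @slot converged logical convergence flag.
#' @seealso [predictPSup()], [nestedFTest()]
#' @export
setClass("SedModelFit",
  representation(beta = "numeric", x = "numeric", mu = "numeric",
                 nu = "numeric", exponentSign = "numeric", rss = "numeric",
                 nObs = "integer", nPar = "integer", free = "character",
                 converged = "logical"))

setValidity("SedModelFit", function(object) {
  msg <- character()
  if (object@beta <= 0) msg <- c(msg, "beta must be positive")
  if (!object@exponentSign %in% c(-1, 1)) msg <- c(msg, "exponentSign must be +1 or -1")
  if (object@rss < 0) msg <- c(msg, "rss must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn SedModelFit-class named parameter vector
#'   `(beta, x, mu, nu)`.
#' @param object a `SedModelFit`.
#' @export
modelParams <- function(object) {
  stopifnot(is(object, "SedModelFit"))
  c(beta = object@beta, x = object@x, mu = object@mu, nu = object@nu)
}

setMethod("show", "SedModelFit", function(object) {
  cat("SedModelFit: pSup(L) = 1 - beta * L^x * exp(sign*(mu + nu*L))\n")
  cat(sprintf("  beta = %.4g  x = %.4g  mu = %.4g  nu = %.4g  (sign %+d)\n",
              object@beta, object@x, object@mu, object@nu,
              as.integer(object@exponentSign)))
  cat(sprintf("  free: %s | rss = %.6g on %d obs | converged: %s\n",
              paste(object@free, collapse = ","), object@rss, object@nObs,
              object@converged))
  invisible(NULL)
})

setMethod("show", "SedSeqExperiment", function(object) {
  callNextMethod()
  cond <- table(colData(object)$condition)
  cat("conditions:", paste(sprintf("%s(%d)", names(cond), cond),
                           collapse = " "), "\n")
  invisible(NULL)
})
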