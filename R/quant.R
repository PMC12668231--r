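#' Prior configuration for mixing-ratio estimation
#'
#' The mixing-ratio model places weakly-informative positive priors on the
#' mixing ratios (centred at 1, unit scale) and a half-Cauchy prior on the
#' NB dispersion. With thousands of genes the likelihood dominates; the
#' ratio priors matter only on degenerate ridges (all genes sharing one
#' supernatant/pellet split), where they resolve the estimate toward equal
#' mixing.
#'
#' @param ratioFamily prior family for the mixing ratios: `"gamma"`
#'   (default; shape `ratioShape`, mean `ratioMean`), `"lognormal"`
#'   (meanlog `log(ratioMean)`, sdlog `ratioScale`), or `"flat"` (improper
#'   uniform on the positive axis, i.e. maximum likelihood).
#' @param ratioShape gamma shape (default 2).
#' @param ratioMean prior mean for both ratios (default 1).
#' @param ratioScale log-normal sdlog (default 1).
#' @param phiScale half-Cauchy scale for the NB dispersion (default 3).
#'
#' @return list of class `priorConfig`.
#' @examples
#' priorConfig()                   # defaults
#' priorConfig(ratioFamily = "flat")  # pure maximum likelihood
#' @export
priorConfig <- function(ratioFamily = c("gamma", "lognormal", "flat"),
                        ratioShape = 2, ratioMean = 1, ratioScale = 1,
                        phiScale = 3) {
  ratioFamily <- match.arg(ratioFamily)
  if (ratioShape <= 0 || ratioMean <= 0 || ratioScale <= 0 || phiScale <= 0) {
    stop("all prior scales must be positive")
  }
  structure(list(ratioFamily = ratioFamily, ratioShape = ratioShape,
                 ratioMean = ratioMean, ratioScale = ratioScale,
                 phiScale = phiScale),
            class = "priorConfig")
}

## log prior density for one mixing ratio a > 0
logPriorRatio <- function(a, priors) {
  switch(priors$ratioFamily,
    gamma = dgamma(a, shape = priors$ratioShape,
                   rate = priors$ratioShape / priors$ratioMean, log = TRUE),
    lognormal = dlnorm(a, meanlog = log(priors$ratioMean),
                       sdlog = priors$ratioScale, log = TRUE),
    flat = 0
  )
}

## half-Cauchy(0, scale) log density on phi > 0
logPriorPhi <- function(phi, priors) {
  dcauchy(phi, 0, priors$phiScale, log = TRUE) + log(2)
}

## joint log-posterior on theta = (log aS, log aP, log phi)
mixingLogPost <- function(theta, T, S, P, priors) {
  aS <- exp(theta[1]); aP <- exp(theta[2]); phi <- exp(theta[3])
  m <- aS * S + aP * P
  if (any(m <= 0) || !all(is.finite(m))) return(-Inf)
  ll <- sum(dnbinom(T, mu = m, size = phi, log = TRUE))
  ll + logPriorRatio(aS, priors) + logPriorRatio(aP, priors) +
    logPriorPhi(phi, priors)
}

#' Estimate per-experiment mixing ratios and NB dispersion
#'
#' Fits the conservation-of-mass count model
#' `T_i ~ NB(mean = aS*S_i + aP*P_i, size = phi)` over all genes whose
#' three fraction counts each exceed `minCount`, using the priors in
#' [priorConfig()]. The mixing ratios `aS`, `aP` recover the original
#' fraction stoichiometry distorted by differential processing of the
#' supernatant and pellet samples. The default mode is MAP (bounded
#' quasi-Newton on the log-parameter scale with random restarts);
#' `mode = "posterior"` runs an adaptive random-walk Metropolis sampler and
#' reports posterior means with 95% intervals.
#'
#' Called on a [SedSeqExperiment-class], each experiment (column) is fit
#' independently and a named `SimpleList` of fits is returned; called on
#' three count vectors, a single [MixingFit-class] is returned.
#'
#' @param object a `SedSeqExperiment`, or the Total count vector.
#' @param sup,pellet supernatant / pellet count vectors (vector interface).
#' @param priors a [priorConfig()].
#' @param minCount filter: a gene enters the fit only when Total, Sup and
#'   Pellet all exceed this value (default 20).
#' @param mode `"map"` (default) or `"posterior"`.
#' @param nRestarts random restarts for the MAP optimizer.
#' @param nIter,burnin posterior-mode sampler settings.
#' @param seed seed for restarts/sampling.
#' @param ... passed through to the vector method.
#'
#' @return A [MixingFit-class] (vector interface) or `SimpleList` of them,
#'   one per experiment.
#' @examples
#' S <- c(100, 10, 50); P <- c(10, 100, 50); T <- c(205, 70, 125)
#' fit <- estimateMixingRatios(T, S, P, minCount = 5,
#'                             priors = priorConfig(ratioFamily = "flat"))
#' mixingRatios(fit)  # ~ (2, 0.5)
#' @export
setGeneric("estimateMixingRatios", function(object, ...)
  standardGeneric("estimateMixingRatios"))

#' @rdname estimateMixingRatios
#' @export
setMethod("estimateMixingRatios", "numeric",
  function(object, sup, pellet, priors = priorConfig(), minCount = 20,
           mode = c("map", "posterior"), nRestarts = 5, nIter = 4000,
           burnin = 1000, seed = NULL, ...) {
    mode <- match.arg(mode)
    T <- object; S <- sup; P <- pellet
    if (any(c(T, S, P) < 0, na.rm = TRUE)) stop("counts must be non-negative")
    keep <- !is.na(T) & !is.na(S) & !is.na(P) &
      T > minCount & S > minCount & P > minCount
    nUsed <- sum(keep)
    if (nUsed < 3) {
      stop(sprintf(
        "only %d gene(s) pass the count filter (need >= 3); lower 'minCount'",
        nUsed))
    }
    T <- T[keep]; S <- S[keep]; P <- P[keep]
    warn <- character()
    splits <- S / (S + P)
    cv <- sd(splits) / mean(splits)
    if (!is.finite(cv) || cv < 0.01) {
      warn <- c(warn,
        "supernatant/pellet splits nearly constant across genes; mixing ratios are only identified up to a ridge resolved by the prior")
    }

    ## moment start: least-squares solution of T ~ aS S + aP P
    X <- cbind(S, P)
    ls <- tryCatch(solve(crossprod(X), crossprod(X, T)),
                   error = function(e) c(1, 1))
    start0 <- log(pmax(c(ls), 1e-3))
    starts <- list(c(start0, log(10)))
    extra <- withSeed(seed, lapply(seq_len(max(0, nRestarts - 1)), function(i)
      c(start0 + rnorm(2, 0, 0.5), log(10) + rnorm(1, 0, 1))))
    starts <- c(starts, extra)

    best <- NULL
    for (st in starts) {
      opt <- tryCatch(
        optim(st, function(th) -mixingLogPost(th, T, S, P, priors),
              method = "L-BFGS-B", lower = rep(-12, 3), upper = rep(12, 3),
              control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
    if (is.null(best)) stop("mixing-ratio optimization failed for all starts")
    th <- best$par
    posterior <- list()

    if (mode == "posterior") {
      draws <- withSeed(seed, mixingSampler(th, T, S, P, priors,
                                            nIter = nIter, burnin = burnin))
      est <- colMeans(draws)
      posterior <- list(
        mean = setNames(est, c("aS", "aP", "phi")),
        ci95 = apply(draws, 2, quantile, c(0.025, 0.975)),
        nDraws = nrow(draws))
      aS <- est[1]; aP <- est[2]; phi <- est[3]
    } else {
      aS <- exp(th[1]); aP <- exp(th[2]); phi <- exp(th[3])
    }
    if (length(warn)) for (w in warn) warning(w, call. = FALSE)
    new("MixingFit", aS = unname(aS), aP = unname(aP), phi = unname(phi),
        nGenesUsed = as.integer(nUsed), objective = -best$value,
        mode = mode, warnings = warn, posterior = posterior)
  })

#' @rdname estimateMixingRatios
#' @export
setMethod("estimateMixingRatios", "SedSeqExperiment",
  function(object, priors = priorConfig(), minCount = 20,
           mode = c("map", "posterior"), seed = NULL, ...) {
    mode <- match.arg(mode)
    fits <- lapply(seq_len(ncol(object)), function(j) {
      estimateMixingRatios(assay(object, "Total")[, j],
                           assay(object, "Sup")[, j],
                           assay(object, "Pellet")[, j],
                           priors = priors, minCount = minCount,
                           mode = mode, seed = childSeed(seed, j), ...)
    })
    SimpleList(setNames(fits, colnames(object)))
  })

## adaptive random-walk Metropolis on (log aS, log aP, log phi);
## returns draws on the natural scale
mixingSampler <- function(init, T, S, P, priors, nIter = 4000, burnin = 1000) {
  d <- length(init)
  cur <- init
  curLp <- mixingLogPost(cur, T, S, P, priors)
  scale <- rep(0.05, d)
  draws <- matrix(NA_real_, nIter, d)
  acc <- 0L
  for (i in seq_len(nIter + burnin)) {
    prop <- cur + rnorm(d, 0, scale)
    lp <- mixingLogPost(prop, T, S, P, priors)
    if (is.finite(lp) && log(runif(1)) < lp - curLp) {
      cur <- prop; curLp <- lp; acc <- acc + 1L
    }
    if (i <= burnin && i %% 100 == 0) {
      rate <- acc / 100; acc <- 0L
      scale <- scale * ifelse(rate > 0.35, 1.3, ifelse(rate < 0.15, 0.7, 1))
    }
    if (i > burnin) draws[i - burnin, ] <- cur
  }
  exp(draws)
}

#' Convert fraction counts to per-gene pSup
#'
#' Applies the mixing-ratio correction to give the proportion of each
#' transcript's molecules in the supernatant:
#' `pSup_i = aS*S_i / (aS*S_i + aP*P_i)`. Genes with zero counts in both
#' S and P are reported as `NA`. The log-odds (`lopsup`) is computed after
#' clipping pSup into `[epsilon, 1 - epsilon]`.
#'
#' Called on a [SedSeqExperiment-class] with the matching list of fits,
#' adds `"psup"` and `"lopsup"` assays and records the fits in
#' `metadata(x)$mixingFits`; called on count vectors, returns a data.frame.
#'
#' @param object a `SedSeqExperiment` or the Sup count vector.
#' @param pellet pellet counts (vector interface).
#' @param fit a [MixingFit-class] (vector interface) or `SimpleList` of
#'   fits, one per experiment column.
#' @param epsilon clipping bound for the log-odds transform.
#' @param ... unused.
#'
#' @return The `SedSeqExperiment` with `psup`/`lopsup` assays, or a
#'   data.frame `psup`, `lopsup`.
#' @examples
#' fit <- new("MixingFit", aS = 2, aP = 0.5, phi = 50, nGenesUsed = 3L,
#'            objective = 0, mode = "map", warnings = character(),
#'            posterior = list())
#' computePSup(c(100, 0), c(10, 25), fit)$psup  # 0.9756, 0
#' @export
setGeneric("computePSup", function(object, ...) standardGeneric("computePSup"))

#' @rdname computePSup
#' @export
setMethod("computePSup", "numeric",
  function(object, pellet, fit, epsilon = 1e-4, ...) {
    S <- object; P <- pellet
    if (any(c(S, P) < 0, na.rm = TRUE)) stop("counts must be non-negative")
    num <- fit@aS * S
    den <- num + fit@aP * P
    psup <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
    data.frame(psup = psup, lopsup = logOdds(psup, eps = epsilon))
  })

#' @rdname computePSup
#' @export
setMethod("computePSup", "SedSeqExperiment",
  function(object, fit, epsilon = 1e-4, ...) {
    stopifnot(length(fit) == ncol(object))
    psup <- lopsup <- matrix(NA_real_, nrow(object), ncol(object),
                             dimnames = dimnames(assay(object, "Sup")))
    for (j in seq_len(ncol(object))) {
      res <- computePSup(assay(object, "Sup")[, j],
                         assay(object, "Pellet")[, j],
                         fit = fit[[j]], epsilon = epsilon)
      psup[, j] <- res$psup
      lopsup[, j] <- res$lopsup
    }
    assays(object)$psup <- psup
    assays(object)$lopsup <- lopsup
    metadata(object)$mixingFits <- fit
    metadata(object)$psupEpsilon <- epsilon
    object
  })

#' Accessors for the pSup assays
#'
#' @param object a [SedSeqExperiment-class] processed by [computePSup()].
#' @return numeric matrix (genes x experiments).
#' @export
psup <- function(object) {
  if (!"psup" %in% assayNames(object)) {
    stop("no 'psup' assay; run computePSup() first")
  }
  assay(object, "psup")
}

#' @rdname psup
#' @export
lopsup <- function(object) {
  if (!"lopsup" %in% assayNames(object)) {
    stop("no 'lopsup' assay; run computePSup() first")
  }
  assay(object, "lopsup")
}

#' pSup from RT-qPCR Cq values relative to a spike-in
#'
#' Relative abundance of the target in each fraction is obtained by the
#' delta-delta-Cq method against the fraction's spike-in:
#' `A_f = efficiency^-(Cq_target,f - Cq_spike,f)`. The pellet abundance is
#' multiplied by `spikeMassRatio` (mass of spike added to the pellet
#' divided by mass added to the supernatant; 1 when equal masses are
#' added), and `pSup = A_S / (A_S + A_P * spikeMassRatio)`.
#'
#' @param cqTargetSup,cqSpikeSup target and spike Cq in the supernatant.
#' @param cqTargetPellet,cqSpikePellet target and spike Cq in the pellet.
#' @param spikeMassRatio pellet/supernatant spike mass ratio (default 1).
#' @param efficiency amplification efficiency per cycle, in (1, 2\].
#'
#' @return list with `psup` and per-fraction relative abundances
#'   `aSup`, `aPellet`.
#' @examples
#' psupFromCq(20, 18, 21, 18)$psup  # 2/3
#' @export
psupFromCq <- function(cqTargetSup, cqSpikeSup, cqTargetPellet, cqSpikePellet,
                       spikeMassRatio = 1, efficiency = 2) {
  if (any(is.na(c(cqSpikeSup, cqSpikePellet)))) {
    stop("missing spike-in Cq value")
  }
  if (efficiency <= 1 || efficiency > 2) stop("'efficiency' must be in (1, 2]")
  aS <- efficiency^(-(cqTargetSup - cqSpikeSup))
  aP <- efficiency^(-(cqTargetPellet - cqSpikePellet))
  list(psup = aS / (aS + aP * spikeMassRatio), aSup = aS, aPellet = aP)
}
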