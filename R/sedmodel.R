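#' Predicted pSup under the biophysical length model
#'
#' The sedimented fraction of a transcript of length L is modeled as
#' `f(L) = beta * L^x * exp(sign * (mu + nu * L))`: a power law of length
#' at baseline, multiplied under condensation-promoting conditions by a
#' per-transcript (`mu`) and per-nucleotide (`nu`) interaction term. Then
#' `pSup(L) = 1 - min(f, 1 - eps)`, with clipping handling parameter
#' regions where the predicted sedimented fraction would exceed 1 (in
#' practice only the longest transcripts).
#'
#' @param L transcript lengths in nt (> 0).
#' @param beta,x baseline parameters (beta > 0, x > 0).
#' @param mu,nu condensation terms; defaults 0 reduce the model to the
#'   baseline power law.
#' @param exponentSign +1 or -1; both groupings of the stress exponent are
#'   supported because the typeset model is ambiguous (see the vignette).
#' @param eps clipping bound keeping pSup inside (0, 1).
#'
#' @return numeric vector of pSup values in (0, 1).
#' @examples
#' predictPSup(500, beta = 1e-3, x = 1)                 # 0.5
#' predictPSup(500, beta = 1e-3, x = 1, mu = log(1.5))  # 0.25
#' @export
predictPSup <- function(L, beta, x, mu = 0, nu = 0, exponentSign = 1,
                        eps = 1e-6) {
  if (any(L <= 0)) stop("'L' must be positive")
  f <- beta * L^x * exp(exponentSign * (mu + nu * L))
  1 - pmin(f, 1 - eps)
}

## least-squares objective on the log-odds pSup scale
sedModelRSS <- function(lopObs, L, beta, x, mu, nu, exponentSign, eps = 1e-6) {
  pred <- predictPSup(L, beta, x, mu, nu, exponentSign, eps)
  sum((lopObs - logOdds(pred, eps = eps))^2)
}

#' Fit the baseline length model of sedimentation
#'
#' Nonlinear least squares for `(beta, x)` on the log-odds pSup scale:
#' minimizes the sum of squared differences between observed
#' `logit(pSup)` and `logit(1 - beta * L^x)`. Optimization runs over
#' `(log beta, log x)` from a grid of multi-starts (log-spaced beta,
#' several exponents) with quasi-Newton refinement, and returns the best
#' fit as a [SedModelFit-class].
#'
#' @param psup per-gene pSup values in (0, 1).
#' @param length transcript lengths in nt.
#' @param weights optional per-gene weights for the squared residuals.
#' @param eps logit clipping bound.
#' @param betaGrid,xGrid multi-start grids.
#'
#' @return A [SedModelFit-class] with `mu = nu = 0` and free parameters
#'   `beta`, `x`.
#' @examples
#' L <- round(seq(300, 5000, length.out = 50))
#' p <- predictPSup(L, beta = 5e-4, x = 1.1)
#' modelParams(fitBaselineSedModel(p, L))[c("beta", "x")]
#' @export
fitBaselineSedModel <- function(psup, length, weights = NULL, eps = 1e-6,
                                betaGrid = 10^seq(-6, -2.5, length.out = 6),
                                xGrid = c(0.5, 1, 1.5)) {
  ok <- !is.na(psup) & !is.na(length) & psup > 0 & psup < 1 & length > 0
  if (sum(ok) < 10) stop("need at least 10 genes with pSup in (0, 1)")
  lop <- logOdds(psup[ok], eps = eps)
  L <- length[ok]
  w <- if (is.null(weights)) rep(1, sum(ok)) else weights[ok]
  ## centred parameterization: log f = a + x*(log L - mean(log L)).
  ## log beta and x are near-collinear in the raw coordinates; centring
  ## orthogonalizes them so quasi-Newton refinement reaches the optimum.
  lbar <- mean(log(L))
  obj <- function(th) {
    f <- exp(th[1] + exp(th[2]) * (log(L) - lbar))
    pred <- 1 - pmin(f, 1 - eps)
    sum(w * (lop - logOdds(pred, eps = eps))^2)
  }
  best <- NULL
  for (b0 in betaGrid) for (x0 in xGrid) {
    a0 <- log(b0) + x0 * lbar
    opt <- tryCatch(
      optim(c(a0, log(x0)), obj, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      opt <- tryCatch(
        optim(opt$par, obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-15)),
        error = function(e) opt)
    }
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("baseline fit failed to converge from any start")
  xHat <- exp(best$par[2])
  new("SedModelFit", beta = exp(best$par[1] - xHat * lbar), x = xHat,
      mu = 0, nu = 0, exponentSign = 1, rss = best$value,
      nObs = as.integer(sum(ok)), nPar = 2L, free = c("beta", "x"),
      converged = best$convergence == 0)
}

#' Fit the stress condensation terms on a fixed baseline
#'
#' With the baseline `(beta, x)` held fixed (estimated on the control
#' condition), fits the enabled subset of the condensation terms
#' `{mu, nu}` to a treatment condition by least squares on the log-odds
#' pSup scale. The reduced model of the nested test is obtained with
#' `fitMu = FALSE` (no length-independent term).
#'
#' @param psup per-gene treatment pSup values in (0, 1).
#' @param length transcript lengths in nt.
#' @param baseline a [SedModelFit-class] from [fitBaselineSedModel()], or
#'   a named vector `c(beta=, x=)`.
#' @param fitMu,fitNu which condensation terms to fit (at least one).
#' @param exponentSign exponent-grouping convention, +1 or -1.
#' @param eps logit clipping bound.
#' @param starts list of start values for `(mu, nu)`.
#'
#' @return A [SedModelFit-class]; disabled terms are fixed at 0.
#' @export
fitStressSedModel <- function(psup, length, baseline, fitMu = TRUE,
                              fitNu = TRUE, exponentSign = 1, eps = 1e-6,
                              starts = list(c(0, 0), c(0.5, 0), c(0, 1e-4))) {
  if (!fitMu && !fitNu) stop("at least one of 'fitMu'/'fitNu' must be TRUE")
  if (is(baseline, "SedModelFit")) {
    beta <- baseline@beta; x <- baseline@x
  } else {
    beta <- baseline[["beta"]]; x <- baseline[["x"]]
  }
  ok <- !is.na(psup) & !is.na(length) & psup > 0 & psup < 1 & length > 0
  if (sum(ok) < 10) stop("need at least 10 genes with pSup in (0, 1)")
  lop <- logOdds(psup[ok], eps = eps)
  L <- length[ok]
  free <- c("mu", "nu")[c(fitMu, fitNu)]
  obj <- function(th) {
    ## optim may strip names; map positionally via `free`
    mu <- if (fitMu) th[match("mu", free)] else 0
    nu <- if (fitNu) th[match("nu", free)] else 0
    pred <- predictPSup(L, beta, x, mu, nu, exponentSign, eps)
    sum((lop - logOdds(pred, eps = eps))^2)
  }
  best <- NULL
  for (st in starts) {
    th0 <- setNames(st[seq_along(free)] * 0, free)
    if (fitMu) th0["mu"] <- st[1]
    if (fitNu) th0["nu"] <- st[2]
    th0 <- th0[free]
    ## per-transcript term is O(1) log units; per-nt term is O(1e-4)
    psc <- c(mu = 1, nu = 1e-4)[free]
    opt <- tryCatch({
      o <- optim(th0, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-13,
                                parscale = psc))
      if (base::length(th0) > 1L) {
        tryCatch(optim(o$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-12,
                                      parscale = psc)),
                 error = function(e) o)
      } else o
    }, error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("stress fit failed to converge from any start")
  th <- setNames(rep(0, 2), c("mu", "nu"))
  th[free] <- best$par
  new("SedModelFit", beta = beta, x = x, mu = unname(th["mu"]),
      nu = unname(th["nu"]), exponentSign = exponentSign, rss = best$value,
      nObs = as.integer(sum(ok)), nPar = as.integer(base::length(free)),
      free = free, converged = TRUE)
}

#' Nested-model F-test
#'
#' Compares a full and a reduced least-squares fit of nested models on the
#' same data: `F = ((rss_reduced - rss_full) / df_num) /
#' (rss_full / df_den)` with `df_num` the difference in free parameters
#' and `df_den = n_obs - p_full`. Used to ask whether the
#' length-independent condensation term is required to explain
#' stress-induced sedimentation.
#'
#' @param full,reduced [SedModelFit-class] objects (or lists with `rss`
#'   and `nPar`), reduced nested within full.
#' @param nObs number of observations; defaults to the full fit's.
#'
#' @return list with `F`, `dfNum`, `dfDen`, `pValue`, `rssFull`,
#'   `rssReduced`.
#' @examples
#' f <- list(rss = 48, nPar = 4L); r <- list(rss = 60, nPar = 3L)
#' nestedFTest(f, r, nObs = 100)$F  # 24
#' @export
nestedFTest <- function(full, reduced, nObs = NULL) {
  getf <- function(o, what) if (is(o, "SedModelFit")) slot(o, what) else o[[what]]
  rssF <- getf(full, "rss"); rssR <- getf(reduced, "rss")
  pF <- getf(full, "nPar"); pR <- getf(reduced, "nPar")
  if (is.null(nObs)) nObs <- getf(full, "nObs")
  if (pR >= pF) stop("reduced model must have fewer free parameters")
  if (rssR < rssF - 1e-8 * max(1, rssF)) {
    stop("rss_reduced < rss_full: models are not nested or optimization failed")
  }
  rssR <- max(rssR, rssF)
  dfNum <- pF - pR
  dfDen <- nObs - pF
  if (dfDen <= 0) stop("non-positive denominator degrees of freedom")
  F <- ((rssR - rssF) / dfNum) / (rssF / dfDen)
  list(F = F, dfNum = dfNum, dfDen = dfDen,
       pValue = pf(F, dfNum, dfDen, lower.tail = FALSE),
       rssFull = rssF, rssReduced = rssR)
}
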