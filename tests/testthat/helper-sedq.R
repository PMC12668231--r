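## Shared test helpers; fixtures are built in code, no files needed.

## rank-based AUROC: probability that a random positive outranks a
## random negative (equivalent to the Mann-Whitney statistic)
auroc <- function(score, positive) {
  ok <- !is.na(score)
  score <- score[ok]; positive <- positive[ok]
  r <- rank(score)
  (mean(r[positive]) - (sum(positive) + 1) / 2) / sum(!positive)
}

## MixingFit with known parameters, bypassing estimation
makeMixingFit <- function(aS, aP, phi = 50) {
  new("MixingFit", aS = aS, aP = aP, phi = phi, nGenesUsed = 0L,
      objective = 0, mode = "map", warnings = character(),
      posterior = list())
}

## linear least-squares oracle for the mixing model on noise-free data:
## solves T = aS*S + aP*P by the normal equations
lsMixingOracle <- function(T, S, P) {
  X <- cbind(S, P)
  sol <- solve(crossprod(X), crossprod(X, T))
  c(aS = sol[1], aP = sol[2])
}

## brute-force windowed mean/SD oracle (O(n^2)) for lengthProfile
bruteLengthProfile <- function(lop, len, windowFraction) {
  logL <- log(len)
  w <- windowFraction * diff(range(logL))
  mu <- sig <- rep(NA_real_, length(lop))
  for (i in seq_along(lop)) {
    inWin <- abs(logL - logL[i]) <= w / 2
    mu[i] <- mean(lop[inWin])
    if (sum(inWin) >= 2) sig[i] <- sd(lop[inWin])
  }
  list(mu = mu, sigma = sig)
}

## brute-force sort/bin/Z oracle for sedScore (supernatant orientation)
bruteSedScore <- function(lopMat, len, ids, binSize) {
  lopMat <- as.matrix(lopMat)
  n <- nrow(lopMat)
  ord <- order(len, ids)
  nBins <- max(1L, n %/% binSize)
  zAll <- matrix(NA_real_, n, ncol(lopMat))
  for (r in seq_len(ncol(lopMat))) {
    for (b in seq_len(nBins)) {
      lo <- (b - 1L) * binSize + 1L
      hi <- if (b == nBins) n else b * binSize
      idx <- ord[lo:hi]
      v <- lopMat[idx, r]
      zAll[idx, r] <- (v - mean(v)) / sd(v)
    }
  }
  rowMeans(zAll)
}
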