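#' Natural log-odds and its inverse
#'
#' `logOdds()` maps a proportion p in (0, 1) to log(p / (1 - p)); `expit()`
#' is the inverse. Proportions are clipped into `[eps, 1 - eps]` before the
#' transform so that boundary pSup values (0 or 1, common for low-count
#' genes) stay finite on the log-odds scale.
#'
#' @param p numeric vector of proportions in \[0, 1\].
#' @param x numeric vector of log-odds values.
#' @param eps clipping bound; values are forced into `[eps, 1 - eps]`.
#'   Use `eps = 0` for the raw transform.
#'
#' @return numeric vector; `logOdds()` errors on values outside \[0, 1\]
#'   (NA values pass through).
#'
#' @examples
#' logOdds(0.5)            # 0
#' expit(logOdds(0.9756))  # 0.9756
#' @export
logOdds <- function(p, eps = 1e-4) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("logOdds(): ", sum(bad), " value(s) outside [0, 1]")
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' @rdname logOdds
#' @export
expit <- function(x) {
  1 / (1 + exp(-x))
}

## Run `expr` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is untouched. seed = NULL uses (and advances) the global RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Derive a distinct, reproducible child seed from a master seed.
## Keeps results within 32-bit integer range.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103515245 + 12345 * k) %% 2147483647L)
}

stopifnotScalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name))
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name))
  }
  invisible(x)
}
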