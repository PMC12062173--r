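## Internal numeric helpers shared across modules.

.EPS <- 1e-12

#' @importFrom stats plogis qlogis optim optimHess dnorm lm pchisq pnorm
#'   quantile rbinom runif rlnorm sd setNames cor var coef vcov
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. Used so that every seeded operation is
## reproducible without clobbering the session RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Nearest-rank percentile: the smallest order statistic whose cumulative
## fraction reaches p (in percent). Matches discrete "75. Per."-style tables.
nearestRankPercentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(rep(NA_real_, length(p)))
  idx <- pmax(1L, pmin(n, as.integer(ceiling(p / 100 * n))))
  x[idx]
}

isSquareSymmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && all(abs(m - t(m)) < tol)
}

isPositiveDefinite <- function(m, tol = 1e-10) {
  if (!isSquareSymmetric(m)) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol)
}

## Cholesky-based PD check + inverse; returns NULL if not PD.
tryCholInverse <- function(m) {
  ch <- tryCatch(chol((m + t(m)) / 2), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  chol2inv(ch)
}

logistic <- function(x) plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
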