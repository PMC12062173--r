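## MAP trait estimation with a multivariate-normal prior, per-dimension SEM,
## and the reliability / T-score conversions.

## Fast MAP core working on the flat bank view. `idx` indexes administered
## items, `resp` is the parallel 0/1 vector. Returns theta, the posterior
## covariance diagonal (SEM^2) and convergence info. The SEM uses the
## observed information (negative Hessian of the log posterior) by default,
## falling back to the expected (Fisher) information if the observed matrix
## is not positive definite -- possible under the 4PL where wrong responses
## on easy items can contribute positive curvature.
mapCore <- function(bm, idx, resp, priorMean, priorPrec, priorCov,
                    init = NULL, information = "observed") {
  D <- bm$D
  if (length(idx) == 0L) {
    return(list(theta = priorMean, sem = sqrt(diag(priorCov)),
                cov = priorCov, converged = TRUE))
  }
  A <- bm$A[idx, , drop = FALSE]
  d <- bm$d[idx]
  lo <- bm$lo[idx]
  span <- bm$up[idx] - lo
  r <- as.numeric(resp)

  clamp <- function(p) pmin(pmax(p, 1e-10), 1 - 1e-10)

  negLogPost <- function(th) {
    pstar <- plogis(drop(A %*% th) + d)
    p <- clamp(lo + span * pstar)
    dv <- th - priorMean
    -(sum(r * log(p) + (1 - r) * log1p(-p)) -
        0.5 * drop(crossprod(dv, priorPrec %*% dv)))
  }
  negGrad <- function(th) {
    pstar <- plogis(drop(A %*% th) + d)
    p <- clamp(lo + span * pstar)
    g <- (r - p) / (p * (1 - p)) * span * pstar * (1 - pstar)
    -(drop(crossprod(A, g)) - drop(priorPrec %*% (th - priorMean)))
  }

  st <- init %||% priorMean
  opt <- optim(st, negLogPost, negGrad, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-10))
  if (opt$convergence != 0) {
    gn <- sqrt(sum(negGrad(opt$par)^2))
    if (gn > 1e-3)
      stop(sprintf(
        "MAP optimisation did not converge (code %d, gradient norm %.3g)",
        opt$convergence, gn))
  }
  th <- opt$par

  pstar <- plogis(drop(A %*% th) + d)
  p <- clamp(lo + span * pstar)
  fis <- (span * pstar * (1 - pstar))^2 / (p * (1 - p))
  covm <- NULL
  if (information == "observed") {
    s <- -(r / p^2 + (1 - r) / (1 - p)^2) * (span * pstar * (1 - pstar))^2 +
      (r - p) / (p * (1 - p)) * span * pstar * (1 - pstar) * (1 - 2 * pstar)
    info <- priorPrec + crossprod(A, -s * A)
    covm <- tryCholInverse(info)
    if (!is.null(covm) && any(diag(covm) <= 0)) covm <- NULL
  }
  if (is.null(covm)) {
    info <- priorPrec + crossprod(A, fis * A)
    covm <- tryCholInverse(info)
    if (is.null(covm)) covm <- solve(info)
  }
  list(theta = th, sem = sqrt(pmax(diag(covm), .EPS)), cov = covm,
       converged = opt$convergence == 0)
}

#' MAP ability estimate
#'
#' Maximises the log-likelihood of the administered responses plus the log
#' multivariate-normal prior density. Per-dimension standard errors are the
#' square roots of the diagonal of the inverse of (prior precision + observed
#' information at the MAP); set `information = "expected"` to use Fisher
#' information instead. With no responses the estimate is the prior mean with
#' SEM 1 per dimension under the standard-normal prior.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param administered ordered character vector of administered item ids.
#' @param responses integer 0/1 vector parallel to `administered`.
#' @param priorMean numeric prior mean (default zero vector).
#' @param priorCov prior covariance (default the bank's trait correlation
#'   matrix); must be positive definite.
#' @param information "observed" (default) or "expected" curvature for the
#'   SEM.
#' @return An \linkS4class{AbilityEstimate}.
#' @examples
#' b <- itemBank(list(itemParameters("i1", 1, 0)), "trait")
#' mapEstimate(b, "i1", 1)  # theta approximately 0.400
#' @export
mapEstimate <- function(bank, administered, responses,
                        priorMean = NULL, priorCov = NULL,
                        information = c("observed", "expected")) {
  information <- match.arg(information)
  if (length(administered) != length(responses))
    stop("administered and responses must have the same length")
  if (length(responses) && !all(responses %in% c(0L, 1L)))
    stop("responses must be coded 0/1")
  D <- nDimensions(bank)
  priorMean <- priorMean %||% rep(0, D)
  priorCov <- priorCov %||% traitCov(bank)
  if (!isPositiveDefinite(priorCov))
    stop("priorCov must be positive definite")
  priorPrec <- solve(priorCov)
  bm <- bankMatrices(bank)
  idx <- match(administered, bm$ids)
  if (anyNA(idx))
    stop("unknown item id(s): ",
         paste(administered[is.na(idx)], collapse = ", "))
  res <- mapCore(bm, idx, responses, priorMean, priorPrec, priorCov,
                 information = information)
  new("AbilityEstimate",
    theta = res$theta,
    sem = res$sem,
    reliability = 1 - res$sem^2,
    tScores = 50 + 10 * res$theta,
    dimensionLabels = dimensionLabels(bank),
    reported = !bank@nuisanceDimensions
  )
}

#' Convert between SEM and reliability
#'
#' On a unit-variance latent scale, \eqn{SEM = \sqrt{1 - Rel}} and
#' \eqn{Rel = 1 - SEM^2}. Reliabilities of 0.75, 0.80, 0.85 and 0.90
#' correspond to SEM values 0.500, 0.447, 0.387 and 0.316.
#'
#' @param rel reliability in [0, 1).
#' @param sem standard error of measurement, nonnegative.
#' @return `semFromReliability` the SEM; `reliabilityFromSem` the
#'   reliability. The two round-trip exactly.
#' @examples
#' semFromReliability(0.80)  # 0.4472136
#' reliabilityFromSem(sqrt(0.15))  # 0.85
#' @export
semFromReliability <- function(rel) {
  if (any(rel < 0) || any(rel >= 1))
    stop("reliability must lie in [0, 1)")
  sqrt(1 - rel)
}

#' @rdname semFromReliability
#' @export
reliabilityFromSem <- function(sem) {
  if (any(sem < 0)) stop("sem must be nonnegative")
  1 - sem^2
}

#' T-score transform
#'
#' Linear transform of the latent scale to the conventional T-metric,
#' \eqn{T = 50 + 10\theta}.
#'
#' @param theta numeric vector of latent trait values.
#' @return Numeric vector of T-scores.
#' @export
tScore <- function(theta) {
  50 + 10 * theta
}
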