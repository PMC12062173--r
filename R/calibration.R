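## Confirmatory MIRT calibration by marginal maximum likelihood:
## EM with fixed-grid quadrature (tensor normal grid up to 3 dimensions,
## seeded quasi-Monte-Carlo integration above that), per-item M-steps under
## the confirmatory loading pattern, weakly-penalised asymptotes on the
## logit scale, optional trait-correlation updates from posterior moments,
## and multi-start estimation keeping the best marginal log-likelihood.

## Quadrature grid for the latent density: points (Q x D) and log prior
## weights under covariance Sigma. Tensor grids reweight under a new Sigma;
## the QMC rule redraws points through the Cholesky factor instead.
makeQuadrature <- function(D, sigma, nQuad, nMC, seed) {
  if (D <= 3L) {
    oneDim <- seq(-5, 5, length.out = nQuad)
    pts <- as.matrix(expand.grid(rep(list(oneDim), D)))
    colnames(pts) <- NULL
    lw <- mvnLogDensity(pts, sigma)
    list(type = "tensor", points = pts, logw = lw - logSumExp(lw))
  } else {
    Z <- withSeed(seed, matrix(stats::rnorm(nMC * D), nMC, D))
    list(type = "qmc", Z = Z, points = Z %*% chol(sigma),
         logw = rep(-log(nMC), nMC))
  }
}

mvnLogDensity <- function(pts, sigma) {
  ch <- chol(sigma)
  half <- backsolve(ch, t(pts), transpose = TRUE)
  -0.5 * colSums(half^2) - sum(log(diag(ch))) -
    0.5 * ncol(pts) * log(2 * pi)
}

requadrate <- function(quad, sigma) {
  if (quad$type == "tensor") {
    lw <- mvnLogDensity(quad$points, sigma)
    quad$logw <- lw - logSumExp(lw)
  } else {
    quad$points <- quad$Z %*% chol(sigma)
  }
  quad
}

## Item probabilities over the grid: returns Q x J matrix.
gridProbs <- function(pars, pts) {
  U <- pts %*% t(pars$A)
  U <- sweep(U, 2L, pars$d, "+")
  pstar <- plogis(U)
  P <- sweep(sweep(pstar, 2L, pars$up - pars$lo, "*"), 2L, pars$lo, "+")
  pmin(pmax(P, 1e-10), 1 - 1e-10)
}

## Per-item M-step objective over the grid: expected complete-data
## log-likelihood + weak logit-normal penalties on free asymptotes.
## Parameter vector: free loadings, intercept, [logit chi], [logit gamma].
itemMStep <- function(par0, freeDims, family, pts, rq, nq, penaltySd) {
  nA <- length(freeDims)
  hasChi <- family %in% c("M3PL", "M4PL")
  hasGma <- family == "M4PL"
  X <- pts[, freeDims, drop = FALSE]
  muChi <- qlogis(0.15)
  muGma <- qlogis(0.95)

  obj <- function(par) {
    a <- par[seq_len(nA)]
    d <- par[nA + 1L]
    chi <- if (hasChi) plogis(par[nA + 2L]) else 0
    gma <- if (hasGma) plogis(par[nA + 2L + hasChi]) else 1
    pstar <- plogis(drop(X %*% a) + d)
    p <- pmin(pmax(chi + (gma - chi) * pstar, 1e-10), 1 - 1e-10)
    ll <- sum(rq * log(p) + (nq - rq) * log1p(-p))
    if (hasChi) ll <- ll - 0.5 * ((par[nA + 2L] - muChi) / penaltySd)^2
    if (hasGma)
      ll <- ll - 0.5 * ((par[nA + 2L + hasChi] - muGma) / penaltySd)^2
    -ll
  }
  opt <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 100, reltol = 1e-9))
  opt$par
}

#' Count the free parameters of a confirmatory model
#'
#' Free loadings (nonzero pattern entries) + one intercept per item +
#' family-dependent asymptotes (M3PL adds one lower asymptote per item,
#' M4PL additionally one upper asymptote per item) + free correlations among
#' content traits when `correlatedTraits` is set.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @return Integer free-parameter count.
#' @examples
#' lp <- matrix(1, 10, 1)
#' countParameters(modelSpec("M2PL", lp))  # 20
#' @export
countParameters <- function(spec) {
  J <- nrow(spec@loadingPattern)
  q <- sum(spec@loadingPattern) + J
  q <- q + switch(spec@family, M2PL = 0L, M3PL = J, M4PL = 2L * J)
  if (spec@correlatedTraits) {
    nContent <- sum(!spec@nuisanceDimensions)
    q <- q + choose(nContent, 2L)
  }
  as.integer(q)
}

#' Degrees of freedom of the M2 statistic
#'
#' The M2 statistic compares J univariate and J(J-1)/2 bivariate margins to
#' their model-implied values, so \eqn{df = J + J(J-1)/2 - q} for q free
#' parameters.
#'
#' @param nItems number of items J.
#' @param nParameters free-parameter count q.
#' @return Integer degrees of freedom.
#' @examples
#' m2DegreesOfFreedom(177, 408)  # 15345
#' @export
m2DegreesOfFreedom <- function(nItems, nParameters) {
  as.integer(nItems + nItems * (nItems - 1) / 2 - nParameters)
}

## Initial parameter set for one start: classical difficulty-based
## intercepts, jittered unit loadings on the pattern.
initParams <- function(responses, spec, jitter) {
  J <- ncol(responses)
  D <- ncol(spec@loadingPattern)
  pbar <- colMeans(responses, na.rm = TRUE)
  pbar <- pmin(pmax(pbar, 0.02), 0.98)
  A <- spec@loadingPattern *
    matrix(exp(jitter), J, D)
  d <- qlogis(pbar) * sqrt(1 + rowSums(A^2))  # probit-style attenuation
  hasChi <- spec@family %in% c("M3PL", "M4PL")
  hasGma <- spec@family == "M4PL"
  list(A = A, d = d,
       lo = rep(if (hasChi) 0.1 else 0, J),
       up = rep(if (hasGma) 0.95 else 1, J))
}

#' Calibrate a confirmatory MIRT model
#'
#' Marginal maximum likelihood via the EM algorithm. The E-step integrates
#' the latent density on a fixed normal grid (tensor product up to three
#' dimensions; a seeded quasi-Monte-Carlo rule above that, where tensor
#' quadrature is infeasible). The M-step maximises each item's expected
#' complete-data log-likelihood under the confirmatory loading pattern, with
#' free asymptotes parameterised on the logit scale under weak normal
#' penalties (sd `penaltySd`) to stabilise the notoriously ill-determined
#' 4PL asymptotes. With `correlatedTraits`, correlations among content
#' traits are updated from posterior moments each iteration. Estimation is
#' repeated from `nStarts` jittered starting points and the best marginal
#' log-likelihood wins; the same seed always reproduces the same solution.
#'
#' Items answered by fewer than `minResponses` respondents or with zero
#' response variance carry no usable information and are flagged for removal
#' rather than estimated.
#'
#' @param responses N x J matrix of 0/1/NA with item ids as column names.
#' @param spec a \linkS4class{ModelSpec}; `loadingPattern` rows must match
#'   the (retained) items.
#' @param nStarts number of random starts.
#' @param seed RNG seed governing starts and any QMC rule.
#' @param nQuad one-dimensional grid size for tensor quadrature.
#' @param nMC number of quasi-Monte-Carlo points for D > 3.
#' @param maxIter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param minResponses minimum respondents per item.
#' @param penaltySd sd of the logit-scale asymptote penalties.
#' @return A \linkS4class{CalibrationFit}.
#' @export
fitMirt <- function(responses, spec, nStarts = 3L, seed = 1,
                    nQuad = 61L, nMC = 2000L, maxIter = 100L, tol = 1e-3,
                    minResponses = 10L, penaltySd = 3) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- sprintf("item_%03d", seq_len(ncol(responses)))
  vals <- responses[!is.na(responses)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("responses must be coded 0/1/NA")
  if (nrow(spec@loadingPattern) != ncol(responses))
    stop("loadingPattern must have one row per response column")

  ## flag degenerate items: too few answers or zero variance
  nAns <- colSums(!is.na(responses))
  v <- apply(responses, 2L, function(x) var(x, na.rm = TRUE))
  bad <- nAns < minResponses | is.na(v) | v == 0
  removed <- colnames(responses)[bad]
  if (all(bad)) stop("no estimable items remain")
  responses <- responses[, !bad, drop = FALSE]
  pattern <- spec@loadingPattern[!bad, , drop = FALSE]
  specUsed <- modelSpec(spec@family, pattern, spec@correlatedTraits,
                        spec@nuisanceDimensions)

  N <- nrow(responses)
  J <- ncol(responses)
  D <- ncol(pattern)
  nuis <- specUsed@nuisanceDimensions
  nQ1 <- if (D == 1L) nQuad else if (D == 2L) 21L else 11L

  Obs <- !is.na(responses)
  X <- responses
  X[!Obs] <- 0
  storage.mode(X) <- "double"
  storage.mode(Obs) <- "double"

  emOneStart <- function(startSeed) {
    jitter <- withSeed(startSeed, stats::rnorm(J * D, 0, 0.3))
    pars <- initParams(responses, specUsed, jitter)
    sigma <- diag(D)
    quad <- makeQuadrature(D, sigma, nQ1, nMC, seed = startSeed)
    hasChi <- specUsed@family %in% c("M3PL", "M4PL")
    hasGma <- specUsed@family == "M4PL"
    llPrev <- -Inf
    ll <- -Inf
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
      P <- gridProbs(pars, quad$points)            # Q x J
      LL <- tcrossprod(X, log(P)) + tcrossprod(Obs - X, log1p(-P))  # N x Q
      LL <- sweep(LL, 2L, quad$logw, "+")
      mx <- apply(LL, 1L, max)
      W <- exp(LL - mx)
      rs <- rowSums(W)
      ll <- sum(log(rs) + mx)
      post <- W / rs                               # N x Q posteriors
      Rq <- crossprod(post, X)                     # Q x J expected correct
      Nq <- crossprod(post, Obs)                   # Q x J expected tries

      for (j in seq_len(J)) {
        freeDims <- which(pattern[j, ] > 0)
        par0 <- c(pars$A[j, freeDims], pars$d[j])
        if (hasChi) par0 <- c(par0, qlogis(pmin(pmax(pars$lo[j], 1e-3),
                                                0.999)))
        if (hasGma) par0 <- c(par0, qlogis(pmin(pmax(pars$up[j], 1e-3),
                                                0.999)))
        est <- itemMStep(par0, freeDims, specUsed@family, quad$points,
                         Rq[, j], Nq[, j], penaltySd)
        nA <- length(freeDims)
        pars$A[j, freeDims] <- est[seq_len(nA)]
        pars$d[j] <- est[nA + 1L]
        if (hasChi) pars$lo[j] <- plogis(est[nA + 2L])
        if (hasGma) pars$up[j] <- plogis(est[nA + 2L + hasChi])
      }

      if (specUsed@correlatedTraits && D > 1L) {
        wq <- colSums(post)
        M2 <- crossprod(quad$points, wq * quad$points) / N
        R <- stats::cov2cor(M2)
        ## nuisance dimensions stay orthogonal to everything
        R[nuis, ] <- 0
        R[, nuis] <- 0
        diag(R) <- 1
        if (isPositiveDefinite(R)) {
          sigma <- R
          quad <- requadrate(quad, sigma)
        }
      }

      if (is.finite(llPrev) && abs(ll - llPrev) < tol) {
        converged <- TRUE
        break
      }
      llPrev <- ll
    }
    list(pars = pars, sigma = sigma, logLik = ll, converged = converged)
  }

  starts <- lapply(seq_len(nStarts), function(s)
    tryCatch(emOneStart(as.integer(seed) + s),
             error = function(e) list(logLik = -Inf, converged = FALSE,
                                      error = conditionMessage(e))))
  lls <- vapply(starts, function(s) s$logLik, numeric(1))
  if (all(!is.finite(lls))) {
    diag_ <- vapply(starts, function(s) s$error %||% "non-finite logLik",
                    character(1))
    stop("no start converged:\n  ",
         paste(sprintf("start %d: %s", seq_along(diag_), diag_),
               collapse = "\n  "))
  }
  best <- starts[[which.max(lls)]]

  dimLabels <- colnames(spec@loadingPattern) %||% paste0("dim", seq_len(D))
  items <- lapply(seq_len(J), function(j) {
    itemParameters(
      itemId = colnames(responses)[j],
      loadings = best$pars$A[j, ],
      intercept = best$pars$d[j],
      lowerAsymptote = best$pars$lo[j],
      upperAsymptote = min(best$pars$up[j], 1),
      primaryDimension = which(pattern[j, ] > 0 & !nuis)[1]
    )
  })
  bank <- itemBank(items, dimensionLabels = dimLabels,
                   traitCov = best$sigma, nuisanceDimensions = nuis,
                   startingItems = setNames(character(0), character(0)))
  new("CalibrationFit",
    bank = bank, spec = specUsed, logLik = best$logLik,
    startLogLiks = lls, removedItems = removed,
    converged = isTRUE(best$converged), nObs = as.integer(N)
  )
}

## Marginal log-likelihood of a calibrated bank on (possibly different)
## responses; used for nesting checks.
marginalLogLik <- function(fit, responses, nQuad = 61L, nMC = 2000L,
                           seed = 1) {
  bm <- bankMatrices(fit@bank)
  D <- bm$D
  nQ1 <- if (D == 1L) nQuad else if (D == 2L) 21L else 11L
  quad <- makeQuadrature(D, fit@bank@traitCov, nQ1, nMC, seed)
  pars <- list(A = bm$A, d = bm$d, lo = bm$lo, up = bm$up)
  Obs <- !is.na(responses)
  X <- responses
  X[!Obs] <- 0
  storage.mode(X) <- "double"
  storage.mode(Obs) <- "double"
  P <- gridProbs(pars, quad$points)
  LL <- tcrossprod(X, log(P)) + tcrossprod(Obs - X, log1p(-P))
  LL <- sweep(LL, 2L, quad$logw, "+")
  mx <- apply(LL, 1L, max)
  sum(log(rowSums(exp(LL - mx))) + mx)
}
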