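## Limited-information goodness of fit: the M2 statistic on first- and
## second-order margins, RMSEA with confidence bounds, SRMSR on
## product-moment residual correlations, and TLI/CFI against an
## independence null on the same margins.
##
## M2 = N e' C e with e the residual margin vector, C = Xi^-1 -
## Xi^-1 D (D' Xi^-1 D)^-1 D' Xi^-1, Xi the multinomial asymptotic
## covariance of the sample margins (entries are model-implied joint
## moments of order up to four), and D the Jacobian of the implied margins
## with respect to the free parameters. Complexity is quadratic in the
## number of margins, intended for test-length banks (J up to a few dozen);
## the degrees-of-freedom arithmetic alone is exposed as
## m2DegreesOfFreedom() and needs no data.

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## Margin index sets: J singletons then all pairs (j < k), as index lists.
marginSets <- function(J) {
  sets <- as.list(seq_len(J))
  for (j in seq_len(J - 1L))
    for (k in (j + 1L):J)
      sets[[length(sets) + 1L]] <- c(j, k)
  sets
}

## Model-implied margins kappa for item probability matrix P (Q x J) and
## normalised weights w.
impliedMargins <- function(P, w, sets) {
  vapply(sets, function(s) {
    if (length(s) == 1L) sum(w * P[, s])
    else sum(w * P[, s[1]] * P[, s[2]])
  }, numeric(1))
}

## Multinomial asymptotic covariance of the sample margins:
## Xi_ab = E[prod over union] - kappa_a kappa_b.
marginCovariance <- function(P, w, sets, kappa) {
  s <- length(sets)
  Xi <- matrix(0, s, s)
  for (a in seq_len(s)) {
    for (b in a:s) {
      un <- union(sets[[a]], sets[[b]])
      m <- w
      for (j in un) m <- m * P[, j]
      Xi[a, b] <- Xi[b, a] <- sum(m) - kappa[a] * kappa[b]
    }
  }
  Xi
}

## Free-parameter vector of a calibrated fit, and the inverse mapping.
## Order: per item (free loadings, intercept, logit chi, logit gamma as the
## family allows), then free content-trait correlations.
packParams <- function(fit) {
  bank <- fit@bank
  spec <- fit@spec
  bm <- bankMatrices(bank)
  hasChi <- spec@family %in% c("M3PL", "M4PL")
  hasGma <- spec@family == "M4PL"
  v <- numeric(0)
  for (j in seq_len(nrow(bm$A))) {
    free <- which(spec@loadingPattern[j, ] > 0)
    v <- c(v, bm$A[j, free], bm$d[j])
    if (hasChi) v <- c(v, qlogis(pmin(pmax(bm$lo[j], 1e-6), 1 - 1e-6)))
    if (hasGma) v <- c(v, qlogis(pmin(pmax(bm$up[j], 1e-6), 1 - 1e-6)))
  }
  if (spec@correlatedTraits) {
    content <- which(!spec@nuisanceDimensions)
    if (length(content) > 1L) {
      R <- traitCov(bank)
      for (i in seq_along(content)[-length(content)])
        for (k in (i + 1L):length(content))
          v <- c(v, R[content[i], content[k]])
    }
  }
  v
}

unpackParams <- function(v, fit) {
  spec <- fit@spec
  bm <- bankMatrices(fit@bank)
  hasChi <- spec@family %in% c("M3PL", "M4PL")
  hasGma <- spec@family == "M4PL"
  pos <- 0L
  for (j in seq_len(nrow(bm$A))) {
    free <- which(spec@loadingPattern[j, ] > 0)
    bm$A[j, free] <- v[pos + seq_along(free)]
    pos <- pos + length(free)
    bm$d[j] <- v[pos + 1L]
    pos <- pos + 1L
    if (hasChi) { bm$lo[j] <- plogis(v[pos + 1L]); pos <- pos + 1L }
    if (hasGma) { bm$up[j] <- plogis(v[pos + 1L]); pos <- pos + 1L }
  }
  sigma <- traitCov(fit@bank)
  if (spec@correlatedTraits) {
    content <- which(!spec@nuisanceDimensions)
    if (length(content) > 1L) {
      for (i in seq_along(content)[-length(content)])
        for (k in (i + 1L):length(content)) {
          pos <- pos + 1L
          sigma[content[i], content[k]] <-
            sigma[content[k], content[i]] <- v[pos]
        }
    }
  }
  list(pars = list(A = bm$A, d = bm$d, lo = bm$lo, up = bm$up),
       sigma = sigma)
}

rmseaFromM2 <- function(m2, df, N) {
  sqrt(max((m2 - df) / (df * N), 0))
}

## 90%-style confidence bounds via noncentral chi-square inversion.
rmseaCI <- function(m2, df, N, level = 0.90) {
  a <- (1 - level) / 2
  bound <- function(prob) {
    if (pchisq(m2, df) < prob) return(0)
    f <- function(l) pchisq(m2, df, ncp = l) - prob
    up <- max(m2 * 2, df + 10)
    while (f(up) > 0) up <- up * 2
    stats::uniroot(f, c(0, up), tol = 1e-8)$root
  }
  lam <- c(bound(1 - a), bound(a))
  sqrt(pmax(lam, 0) / (df * N))
}

#' Limited-information fit indices
#'
#' Computes the M2 statistic on univariate and bivariate response margins
#' for a calibrated model, with df = J + J(J-1)/2 − q, RMSEA
#' \eqn{= \sqrt{\max((M_2 - df)/(df\,N), 0)}} with noncentrality-based
#' confidence bounds, the SRMSR over residual product-moment correlations,
#' and TLI/CFI against an independence null with free item margins evaluated
#' on the same statistic. Requires complete (no-missing) responses, the same
#' used for fitting.
#'
#' @param fit a \linkS4class{CalibrationFit}.
#' @param responses the complete N x J 0/1 matrix the model was fitted to.
#' @param nQuad,nMC,seed quadrature controls as in [fitMirt()].
#' @param label tag carried into comparison tables.
#' @return A \linkS4class{FitIndices}.
#' @export
fitIndices <- function(fit, responses, nQuad = 61L, nMC = 2000L, seed = 1,
                       label = fit@spec@family) {
  responses <- as.matrix(responses)
  if (anyNA(responses))
    stop("fit indices require complete responses (no missing cells)")
  ids <- itemIds(fit@bank)
  if (!is.null(colnames(responses)))
    responses <- responses[, ids, drop = FALSE]
  N <- nrow(responses)
  J <- ncol(responses)
  q <- countParameters(fit@spec)
  sets <- marginSets(J)
  s <- length(sets)
  df <- s - q
  if (df <= 0)
    stop("nonpositive degrees of freedom (", df, "): indices undefined")

  D <- nDimensions(fit@bank)
  nQ1 <- if (D == 1L) nQuad else if (D == 2L) 21L else 11L
  quad <- makeQuadrature(D, traitCov(fit@bank), nQ1, nMC, seed)
  quad$logw <- quad$logw - logSumExp(quad$logw)
  w <- exp(quad$logw)

  marginsAt <- function(v) {
    up <- unpackParams(v, fit)
    qd <- requadrate(quad, up$sigma)
    qd$logw <- qd$logw - logSumExp(qd$logw)
    P <- gridProbs(up$pars, qd$points)
    impliedMargins(P, exp(qd$logw), sets)
  }

  v0 <- packParams(fit)
  bm <- bankMatrices(fit@bank)
  P <- gridProbs(list(A = bm$A, d = bm$d, lo = bm$lo, up = bm$up),
                 quad$points)
  kappa <- impliedMargins(P, w, sets)

  phat <- vapply(sets, function(st) {
    if (length(st) == 1L) mean(responses[, st])
    else mean(responses[, st[1]] * responses[, st[2]])
  }, numeric(1))
  e <- phat - kappa

  Xi <- marginCovariance(P, w, sets, kappa)

  ## numerical Jacobian, central differences
  h <- 1e-5
  Delta <- matrix(0, s, length(v0))
  for (r in seq_along(v0)) {
    vp <- v0; vp[r] <- vp[r] + h
    vm <- v0; vm[r] <- vm[r] - h
    Delta[, r] <- (marginsAt(vp) - marginsAt(vm)) / (2 * h)
  }

  XiInv <- tryCholInverse(Xi) %||% MASS::ginv(Xi)
  XtXiX <- crossprod(Delta, XiInv %*% Delta)
  XtXiXinv <- tryCholInverse(XtXiX) %||% MASS::ginv(XtXiX)
  Ce <- XiInv %*% e -
    XiInv %*% Delta %*% (XtXiXinv %*% crossprod(Delta, XiInv %*% e))
  m2 <- max(N * drop(crossprod(e, Ce)), 0)
  p <- pchisq(m2, df, lower.tail = FALSE)

  ## SRMSR on product-moment residual correlations
  srmsr <- srmsrFromMargins(phat, kappa, sets, J)

  ## independence null with free item margins on the same statistic
  p1 <- phat[seq_len(J)]
  kappa0 <- c(p1, vapply(sets[(J + 1L):s], function(st)
    p1[st[1]] * p1[st[2]], numeric(1)))
  P0 <- matrix(p1, nrow = 1L)
  Xi0 <- marginCovariance(P0, 1, sets, kappa0)
  Delta0 <- matrix(0, s, J)
  for (r in seq_len(J)) {
    Delta0[r, r] <- 1
  }
  idx <- J
  for (j in seq_len(J - 1L))
    for (k in (j + 1L):J) {
      idx <- idx + 1L
      Delta0[idx, j] <- p1[k]
      Delta0[idx, k] <- p1[j]
    }
  e0 <- phat - kappa0
  Xi0Inv <- tryCholInverse(Xi0) %||% MASS::ginv(Xi0)
  XtX0 <- crossprod(Delta0, Xi0Inv %*% Delta0)
  XtX0inv <- tryCholInverse(XtX0) %||% MASS::ginv(XtX0)
  Ce0 <- Xi0Inv %*% e0 -
    Xi0Inv %*% Delta0 %*% (XtX0inv %*% crossprod(Delta0, Xi0Inv %*% e0))
  m20 <- max(N * drop(crossprod(e0, Ce0)), 0)
  df0 <- s - J

  tli <- ((m20 / df0) - (m2 / df)) / ((m20 / df0) - 1)
  cfi <- 1 - max(m2 - df, 0) / max(m20 - df0, m2 - df, .EPS)

  new("FitIndices",
    m2 = m2, df = as.numeric(df), p = p,
    rmsea = rmseaFromM2(m2, df, N), rmseaCI = rmseaCI(m2, df, N),
    srmsr = srmsr, tli = tli, cfi = cfi,
    logLik = fit@logLik, nObs = as.integer(N),
    nParameters = as.integer(q), label = label
  )
}

srmsrFromMargins <- function(phat, kappa, sets, J) {
  resid2 <- numeric(0)
  for (a in (J + 1L):length(sets)) {
    j <- sets[[a]][1]
    k <- sets[[a]][2]
    sObs <- sqrt(phat[j] * (1 - phat[j]) * phat[k] * (1 - phat[k]))
    sMod <- sqrt(kappa[j] * (1 - kappa[j]) * kappa[k] * (1 - kappa[k]))
    rObs <- (phat[a] - phat[j] * phat[k]) / sObs
    rMod <- (kappa[a] - kappa[j] * kappa[k]) / sMod
    resid2 <- c(resid2, (rObs - rMod)^2)
  }
  sqrt(mean(resid2))
}

#' Compare calibrated models
#'
#' Orders a set of fits by a fit criterion (default SRMSR ascending, the
#' criterion prioritised for model selection) and tabulates all indices.
#' Ties keep the input order.
#'
#' @param fits list of \linkS4class{FitIndices}.
#' @param criterion one of "srmsr", "rmsea", "m2", "tli", "cfi", "logLik".
#' @return data.frame, one row per fit, best first.
#' @export
compareModels <- function(fits, criterion = c("srmsr", "rmsea", "m2",
                                              "tli", "cfi", "logLik")) {
  criterion <- match.arg(criterion)
  if (!length(fits)) stop("no fits supplied")
  if (!all(vapply(fits, is, logical(1), "FitIndices")))
    stop("fits must be FitIndices objects")
  ns <- vapply(fits, function(f) f@nObs, integer(1))
  if (length(unique(ns)) > 1L)
    stop("fits were computed on different response sets (N differs)")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(label = f@label, nParameters = f@nParameters,
               m2 = f@m2, df = f@df, p = f@p, rmsea = f@rmsea,
               rmseaLB = f@rmseaCI[1], rmseaUB = f@rmseaCI[2],
               srmsr = f@srmsr, tli = f@tli, cfi = f@cfi,
               logLik = f@logLik, stringsAsFactors = FALSE)
  }))
  key <- tab[[switch(criterion, m2 = "m2", criterion)]]
  decreasing <- criterion %in% c("tli", "cfi", "logLik")
  ord <- order(if (decreasing) -key else key, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
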