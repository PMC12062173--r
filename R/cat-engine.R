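## Adaptive session machinery: age-group starting items, information-based
## next-item selection (D/T/A/W/E and posterior-weighted variants), the
## staged SEM stopping rule, and the session loop.
##
## All selection criteria operate on M = prior precision + accumulated
## Fisher information + candidate Fisher information, evaluated at the
## current MAP; the *P variants average the criterion over a fixed stencil of
## posterior quadrature points centred at the MAP. Because every candidate's
## information is the rank-one matrix c_j a_j a_j', the determinant, trace
## and A criteria reduce to cheap rank-one updates.

.SELECTION_RULES <- c("D", "T", "A", "W", "E", "TP", "AP", "WP", "EP")

## Criterion values for every candidate at one theta. Returns the numeric
## criterion (larger is better) per candidate row of Acand.
ruleCriterion <- function(base, Acand, ccand, rule, w) {
  Mb <- base$M
  Minv <- base$Minv
  q <- rowSums((Acand %*% Minv) * Acand)
  switch(rule,
    D = base$logdet + log1p(ccand * q),
    T = base$tr + ccand * rowSums(Acand^2),
    A = {
      m2 <- rowSums((Acand %*% Minv)^2)
      -(base$trinv - ccand * m2 / (1 + ccand * q))
    },
    W = base$wMw + ccand * drop(Acand %*% w)^2,
    E = {
      vapply(seq_len(nrow(Acand)), function(i) {
        Mi <- Mb + ccand[i] * tcrossprod(Acand[i, ])
        min(eigen((Mi + t(Mi)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values)
      }, numeric(1))
    },
    stop("unknown selection rule: ", rule)
  )
}

## Precompute the per-theta base quantities shared by all candidates.
ruleBase <- function(bm, adminIdx, th, priorPrec, w) {
  cc <- bankInfoCoef(bm, th)
  M <- priorPrec
  if (length(adminIdx)) {
    Aa <- bm$A[adminIdx, , drop = FALSE]
    M <- M + crossprod(Aa, cc[adminIdx] * Aa)
  }
  Minv <- tryCholInverse(M)
  if (is.null(Minv)) {
    warning("information matrix numerically singular; using pseudo-inverse")
    Minv <- MASS::ginv(M)
  }
  list(M = M, Minv = Minv, cc = cc,
       logdet = determinant(M, logarithm = TRUE)$modulus[1],
       tr = sum(diag(M)), trinv = sum(diag(Minv)),
       wMw = if (!is.null(w)) drop(crossprod(w, M %*% w)) else NA_real_)
}

## Posterior quadrature stencil for the *P rules: the MAP plus +/- 1 current
## posterior SD along each axis, weighted by the (unnormalised) posterior
## density of theta given the responses so far.
posteriorStencil <- function(bm, adminIdx, resp, th, priorMean, priorPrec,
                             covDiag) {
  D <- bm$D
  step <- sqrt(pmax(covDiag, 1e-6))
  pts <- matrix(rep(th, 2L * D + 1L), ncol = D, byrow = TRUE)
  for (k in seq_len(D)) {
    pts[2L * k, k] <- th[k] + step[k]
    pts[2L * k + 1L, k] <- th[k] - step[k]
  }
  logw <- apply(pts, 1L, function(tg) {
    dv <- tg - priorMean
    lp <- -0.5 * drop(crossprod(dv, priorPrec %*% dv))
    if (length(adminIdx)) {
      pr <- bankProb(bm, tg)
      p <- pmin(pmax(pr$p[adminIdx], 1e-10), 1 - 1e-10)
      lp <- lp + sum(resp * log(p) + (1 - resp) * log1p(-p))
    }
    lp
  })
  wts <- exp(logw - max(logw))
  list(points = pts, weights = wts / sum(wts))
}

## Pick the next item among candidates (bank row indices). Deterministic
## tie-break: lowest item index.
selectNextInternal <- function(bm, adminIdx, resp, th, priorMean, priorPrec,
                               rule, candIdx, w = NULL, covDiag = NULL) {
  if (!length(candIdx)) stop("no unadministered items remain")
  if (length(candIdx) == 1L) return(candIdx)
  posteriorRule <- rule %in% c("TP", "AP", "WP", "EP")
  baseRule <- if (posteriorRule) substr(rule, 1L, 1L) else rule

  if (!posteriorRule) {
    base <- ruleBase(bm, adminIdx, th, priorPrec, w)
    score <- ruleCriterion(base, bm$A[candIdx, , drop = FALSE],
                           base$cc[candIdx], baseRule, w)
  } else {
    st <- posteriorStencil(bm, adminIdx, resp, th, priorMean, priorPrec,
                           covDiag %||% diag(solve(priorPrec)))
    score <- numeric(length(candIdx))
    for (g in seq_len(nrow(st$points))) {
      if (st$weights[g] < 1e-12) next
      base <- ruleBase(bm, adminIdx, st$points[g, ], priorPrec, w)
      score <- score + st$weights[g] *
        ruleCriterion(base, bm$A[candIdx, , drop = FALSE],
                      base$cc[candIdx], baseRule, w)
    }
  }
  candIdx[which.max(score)]
}

## Staged stop check on the SEM history (k x D matrix). Returns
## list(stop, reason).
stopCheckInternal <- function(semHist, k, cfg, reportedIdx, exhausted) {
  thr <- if (k <= cfg@stage1Through) cfg@stage1Threshold else
    cfg@stage2Threshold
  stage <- if (k <= cfg@stage1Through) "stage1_sem" else "stage2_sem"
  sems <- semHist[k, reportedIdx]
  if (all(sems < thr)) return(list(stop = TRUE, reason = stage))
  if (k >= cfg@stabilityStart && k >= cfg@stabilityWindow) {
    win <- semHist[(k - cfg@stabilityWindow + 1L):k, reportedIdx,
                   drop = FALSE]
    ranges <- apply(win, 2L, function(x) max(x) - min(x))
    if (sum(ranges^2) < cfg@stabilityThreshold)
      return(list(stop = TRUE, reason = "stability"))
  }
  if (exhausted) return(list(stop = TRUE, reason = "bank_exhausted"))
  list(stop = FALSE, reason = "")
}

## Full fast session loop shared by the public runSession() and the Monte
## Carlo simulator. respondFun(bankRowIndex, prob) must return 0 or 1.
runSessionInternal <- function(bm, startIdx, respondFun, rule, cfg,
                               priorMean, priorCov, reportedIdx,
                               w = NULL, information = "observed") {
  J <- nrow(bm$A)
  D <- bm$D
  priorPrec <- solve(priorCov)
  adminIdx <- integer(0)
  resp <- integer(0)
  thetaHist <- matrix(NA_real_, J, D)
  semHist <- matrix(NA_real_, J, D)
  th <- priorMean
  covDiag <- diag(priorCov)
  nextIdx <- startIdx
  reason <- "bank_exhausted"
  k <- 0L

  repeat {
    pr <- bankProb(bm, th)
    r <- respondFun(nextIdx, pr$p[nextIdx])
    adminIdx <- c(adminIdx, nextIdx)
    resp <- c(resp, as.integer(r))
    k <- k + 1L
    est <- mapCore(bm, adminIdx, resp, priorMean, priorPrec, priorCov,
                   init = th, information = information)
    th <- est$theta
    covDiag <- diag(est$cov)
    thetaHist[k, ] <- th
    semHist[k, ] <- est$sem
    chk <- stopCheckInternal(semHist, k, cfg, reportedIdx,
                             exhausted = k == J)
    if (chk$stop) {
      reason <- chk$reason
      break
    }
    cand <- setdiff(seq_len(J), adminIdx)
    nextIdx <- selectNextInternal(bm, adminIdx, resp, th, priorMean,
                                  priorPrec, rule, cand, w, covDiag)
  }
  list(adminIdx = adminIdx, responses = resp,
       thetaHistory = thetaHist[seq_len(k), , drop = FALSE],
       semHistory = semHist[seq_len(k), , drop = FALSE],
       stopReason = reason)
}

## Resolve an age (e.g. "4;6", "7;2", 5, "5") to the bank's age-group label
## under the three-bucket convention: 4 years and younger, 5 years, 6 years
## and older.
resolveAgeGroup <- function(bank, ageGroup) {
  starts <- startingItems(bank)
  if (!length(starts)) stop("bank defines no starting items")
  key <- as.character(ageGroup)
  if (key %in% names(starts)) return(key)
  years <- if (grepl(";", key)) {
    suppressWarnings(as.integer(strsplit(key, ";", fixed = TRUE)[[1]][1]))
  } else {
    suppressWarnings(floor(as.numeric(key)))
  }
  if (is.na(years)) stop("unmapped age group: ", ageGroup)
  lab <- if (years <= 4) "4" else if (years == 5) "5" else "6"
  if (!lab %in% names(starts))
    stop("bank defines no starting item for age group \"", lab, "\"")
  lab
}

#' Designated starting item for an age group
#'
#' Each age group (4 years and younger, 5 years, 6 years and older) has a
#' single fixed starting item; ages given as "years;months" strings or
#' numbers are bucketed accordingly.
#'
#' @param bank an \linkS4class{ItemBank} with starting items defined.
#' @param ageGroup age-group label, age in years, or "years;months".
#' @return The starting item id.
#' @examples
#' \dontrun{selectStartingItem(bank, "4;6")}
#' @export
selectStartingItem <- function(bank, ageGroup) {
  lab <- resolveAgeGroup(bank, ageGroup)
  unname(startingItems(bank)[lab])
}

#' Begin an adaptive session
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param ageGroup examinee age group (used for the starting item).
#' @param rule selection rule, one of D, T, A, W, E, TP, AP, WP, EP.
#' @param stopConfig a \linkS4class{StopRuleConfig}.
#' @param priorMean prior mean vector (default zero).
#' @return A fresh \linkS4class{CatSession}.
#' @export
catSession <- function(bank, ageGroup, rule = "AP",
                       stopConfig = stopRuleConfig(),
                       priorMean = rep(0, nDimensions(bank))) {
  rule <- match.arg(rule, .SELECTION_RULES)
  D <- nDimensions(bank)
  new("CatSession",
    bank = bank, ageGroup = as.character(ageGroup),
    administered = character(0), responses = integer(0),
    thetaHistory = matrix(numeric(0), 0L, D),
    semHistory = matrix(numeric(0), 0L, D),
    rule = rule, stopConfig = stopConfig,
    priorMean = priorMean, stopped = FALSE, stopReason = ""
  )
}

sessionReported <- function(session) {
  rd <- session@stopConfig@reportedDimensions
  if (length(rd)) rd else reportedDimensions(session@bank)
}

#' Select the next item of a session
#'
#' With nothing administered yet, returns the age group's starting item.
#' Otherwise maximises the configured criterion over the unadministered
#' candidates on M = prior precision + accumulated information + candidate
#' information at the current MAP: D maximises det(M), T the trace, A
#' \eqn{-\mathrm{tr}(M^{-1})}, E the smallest eigenvalue, W
#' \eqn{w^\top M w}; the *P variants average the same criterion over a fixed
#' posterior quadrature stencil centred at the MAP. Ties break to the lowest
#' bank index.
#'
#' @param session a \linkS4class{CatSession}.
#' @param rule optional rule override.
#' @param weights optional weight vector for the W/WP rules; defaults to
#'   equal weights on the reported dimensions.
#' @return The selected item id.
#' @export
nextItem <- function(session, rule = session@rule, weights = NULL) {
  rule <- match.arg(rule, .SELECTION_RULES)
  bank <- session@bank
  if (length(session@administered) == 0L)
    return(selectStartingItem(bank, session@ageGroup))
  bm <- bankMatrices(bank)
  adminIdx <- match(session@administered, bm$ids)
  cand <- setdiff(seq_along(bm$ids), adminIdx)
  if (!length(cand)) stop("no unadministered items remain")
  priorPrec <- solve(traitCov(bank))
  k <- length(adminIdx)
  th <- session@thetaHistory[k, ]
  w <- weights %||% defaultWeights(bank, sessionReported(session))
  sel <- selectNextInternal(bm, adminIdx, session@responses, th,
                            session@priorMean, priorPrec, rule, cand, w,
                            covDiag = session@semHistory[k, ]^2)
  bm$ids[sel]
}

defaultWeights <- function(bank, reportedIdx) {
  w <- rep(0, nDimensions(bank))
  w[reportedIdx] <- 1 / sqrt(length(reportedIdx))
  w
}

#' Administer an item and rescore the session
#'
#' Appends the response, recomputes the MAP estimate and SEMs, and refreshes
#' the stop status. Difficulty adaptation is emergent: after a correct
#' answer the ability estimate rises and harder items become more
#' informative, after an incorrect answer easier ones.
#'
#' @param session a running \linkS4class{CatSession}.
#' @param itemId the item to administer (must not have been administered).
#' @param response 0 or 1.
#' @return The updated \linkS4class{CatSession}.
#' @export
administer <- function(session, itemId, response) {
  if (session@stopped)
    stop("session already stopped (", session@stopReason, ")")
  if (itemId %in% session@administered)
    stop("item \"", itemId, "\" was already administered")
  if (!response %in% c(0L, 1L)) stop("response must be 0 or 1")
  bank <- session@bank
  administered <- c(session@administered, itemId)
  responses <- c(session@responses, as.integer(response))
  est <- mapEstimate(bank, administered, responses,
                     priorMean = session@priorMean)
  session@administered <- administered
  session@responses <- responses
  session@thetaHistory <- rbind(session@thetaHistory, unname(theta(est)))
  session@semHistory <- rbind(session@semHistory, unname(sem(est)))
  chk <- shouldStop(session)
  session@stopped <- chk$stop
  session@stopReason <- chk$reason
  validObject(session)
  session
}

#' Evaluate the staged stopping rule
#'
#' Stage 1 (through item `stage1Through`, default 49): stop once every
#' reported dimension has SEM below `stage1Threshold`. Stage 2 (later items):
#' the looser `stage2Threshold` applies. From `stabilityStart` on, the
#' session additionally stops when the sum over reported dimensions of the
#' squared SEM ranges over the last `stabilityWindow` items falls below
#' `stabilityThreshold`. A session with no remaining items always stops
#' (`bank_exhausted`).
#'
#' @param session a \linkS4class{CatSession} with at least one item
#'   administered.
#' @param config optional \linkS4class{StopRuleConfig} override.
#' @return list(stop = logical, reason = character).
#' @export
shouldStop <- function(session, config = session@stopConfig) {
  k <- length(session@administered)
  if (k < 1L) stop("no items administered yet")
  rd <- config@reportedDimensions
  if (!length(rd)) rd <- reportedDimensions(session@bank)
  exhausted <- k >= length(bankItems(session@bank))
  stopCheckInternal(session@semHistory, k, config, rd, exhausted)
}

#' Run a complete adaptive session
#'
#' Drives a session from the starting item to termination against a
#' responder: either a `respond` function (called with the item id and the
#' model probability at the current estimate, returning 0/1) or a true trait
#' vector `trueTheta`, in which case responses are simulated from the 4PL
#' model (seeded).
#'
#' @inheritParams catSession
#' @param respond optional function(itemId, prob) -> 0/1.
#' @param trueTheta optional true trait vector for a simulated respondent.
#' @param seed RNG seed for the simulated respondent.
#' @param weights optional W-rule weight vector.
#' @return A completed \linkS4class{CatSession}.
#' @export
runSession <- function(bank, ageGroup, rule = "AP",
                       stopConfig = stopRuleConfig(),
                       respond = NULL, trueTheta = NULL, seed = NULL,
                       priorMean = rep(0, nDimensions(bank)),
                       weights = NULL) {
  rule <- match.arg(rule, .SELECTION_RULES)
  if (is.null(respond) && is.null(trueTheta))
    stop("provide either a respond function or trueTheta")
  bm <- bankMatrices(bank)
  startIdx <- match(selectStartingItem(bank, ageGroup), bm$ids)
  rd <- stopConfig@reportedDimensions
  if (!length(rd)) rd <- reportedDimensions(bank)
  w <- weights %||% defaultWeights(bank, rd)

  if (is.null(respond)) {
    ptrue <- bankProb(bm, trueTheta)$p
    u <- withSeed(seed, runif(length(ptrue)))
    respond <- function(idx, prob) as.integer(u[idx] < ptrue[idx])
    respondFun <- function(idx, prob) respond(idx, prob)
  } else {
    respondFun <- function(idx, prob) {
      r <- respond(bm$ids[idx], prob)
      if (!r %in% c(0L, 1L)) stop("responder must return 0 or 1")
      as.integer(r)
    }
  }
  res <- runSessionInternal(bm, startIdx, respondFun, rule, stopConfig,
                            priorMean, traitCov(bank), rd, w)
  new("CatSession",
    bank = bank, ageGroup = as.character(ageGroup),
    administered = bm$ids[res$adminIdx],
    responses = res$responses,
    thetaHistory = res$thetaHistory,
    semHistory = res$semHistory,
    rule = rule, stopConfig = stopConfig, priorMean = priorMean,
    stopped = TRUE, stopReason = res$stopReason
  )
}
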