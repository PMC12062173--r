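## Monte Carlo CAT evaluation: response simulation, per-simulee session runs
## with the staged or single-threshold stopping rules, the aggregate
## statistic set used for rule comparison, and the starting-item regression.

#' Simulate a full response vector
#'
#' Draws one Bernoulli response per bank item at a fixed true trait vector,
#' with success probability given by the 4PL model. Reproducible by seed.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param thetaTrue true trait vector.
#' @param seed RNG seed.
#' @return Named integer 0/1 vector over the bank's items.
#' @export
simulateResponses <- function(bank, thetaTrue, seed = NULL) {
  bm <- bankMatrices(bank)
  p <- bankProb(bm, thetaTrue)$p
  r <- withSeed(seed, rbinom(length(p), 1L, p))
  setNames(as.integer(r), bm$ids)
}

#' Draw a simulee population
#'
#' @param n number of simulees.
#' @param mean prior mean vector.
#' @param cov positive-definite prior covariance.
#' @param seed RNG seed.
#' @return n x D numeric matrix of true trait vectors.
#' @export
generateSimulees <- function(n, mean, cov, seed = NULL) {
  if (!isPositiveDefinite(cov)) stop("cov must be positive definite")
  D <- length(mean)
  if (n == 0L) return(matrix(numeric(0), 0L, D))
  m <- withSeed(seed, MASS::mvrnorm(n, mu = mean, Sigma = cov))
  if (n == 1L) m <- matrix(m, 1L, D)
  colnames(m) <- colnames(cov)
  m
}

## Aggregate statistic set for item counts (nearest-rank percentiles).
itemCountStats <- function(counts, bankSize) {
  pct <- nearestRankPercentile(counts, c(75, 80, 85, 90, 95))
  c(mean = mean(counts), sd = sd(counts), min = min(counts),
    median = nearestRankPercentile(counts, 50),
    p75 = pct[1], p80 = pct[2], p85 = pct[3], p90 = pct[4], p95 = pct[5],
    max = max(counts), fracFullBank = mean(counts >= bankSize))
}

reliabilityStatsMatrix <- function(rel) {
  stats <- apply(rel, 2L, function(x) {
    c(mean = mean(x), sd = sd(x), min = min(x),
      p5 = nearestRankPercentile(x, 5),
      p25 = nearestRankPercentile(x, 25),
      p50 = nearestRankPercentile(x, 50),
      p75 = nearestRankPercentile(x, 75),
      p95 = nearestRankPercentile(x, 95),
      max = max(x))
  })
  t(stats)
}

#' Monte Carlo CAT simulation
#'
#' Runs a complete adaptive session for every simulee and aggregates the
#' per-simulee item counts and terminal reliabilities into the statistic set
#' used for selection/stopping-rule comparison: mean, SD, min, median,
#' 75/80/85/90/95th nearest-rank percentiles, max and the fraction of
#' simulees requiring the full bank; plus per-dimension reliability
#' statistics (mean, SD, min, 5/25/50/75/95th percentiles, max) at
#' termination.
#'
#' Each simulee's responses are pregenerated from the 4PL model at their true
#' trait vector under `seed`, so runs differing only in the stopping rule
#' administer identical item/response prefixes (paired comparison).
#'
#' @param bank an \linkS4class{ItemBank} with starting items.
#' @param simulees n x D matrix of true trait vectors (or an
#'   \linkS4class{ItemBank}-compatible draw from [generateSimulees()]).
#' @param rule selection rule.
#' @param stopConfig a \linkS4class{StopRuleConfig}.
#' @param seed base RNG seed; simulee i uses seed + i.
#' @param ageGroups character vector of age-group labels per simulee;
#'   defaults to a seeded uniform draw over the bank's groups.
#' @param keepSessions logical; retain per-simulee session logs.
#' @param information "observed" or "expected" SEM curvature.
#' @return A \linkS4class{SimulationSummary}.
#' @export
runCatSimulation <- function(bank, simulees, rule = "AP",
                             stopConfig = stopRuleConfig(), seed = 1,
                             ageGroups = NULL, keepSessions = FALSE,
                             information = "observed") {
  rule <- match.arg(rule, .SELECTION_RULES)
  n <- nrow(simulees)
  if (n == 0L) stop("no simulees supplied")
  bm <- bankMatrices(bank)
  J <- length(bm$ids)
  rd <- stopConfig@reportedDimensions
  if (!length(rd)) rd <- reportedDimensions(bank)
  w <- defaultWeights(bank, rd)
  priorMean <- rep(0, nDimensions(bank))
  groups <- names(startingItems(bank))
  if (is.null(ageGroups)) {
    ageGroups <- withSeed(seed, sample(groups, n, replace = TRUE))
  }
  startIdxByGroup <- vapply(groups, function(g)
    match(startingItems(bank)[[g]], bm$ids), integer(1))

  counts <- integer(n)
  reasons <- character(n)
  rel <- matrix(NA_real_, n, length(rd),
                dimnames = list(NULL, dimensionLabels(bank)[rd]))
  sessions <- if (keepSessions) vector("list", n) else list()

  for (i in seq_len(n)) {
    ptrue <- bankProb(bm, simulees[i, ])$p
    u <- withSeed(seed + i, runif(J))
    respondFun <- function(idx, prob) as.integer(u[idx] < ptrue[idx])
    res <- runSessionInternal(
      bm, startIdxByGroup[[resolveAgeGroup(bank, ageGroups[i])]],
      respondFun, rule, stopConfig, priorMean, traitCov(bank), rd, w,
      information = information
    )
    k <- length(res$adminIdx)
    counts[i] <- k
    reasons[i] <- res$stopReason
    rel[i, ] <- 1 - res$semHistory[k, rd]^2
    if (keepSessions) {
      sessions[[i]] <- list(
        items = bm$ids[res$adminIdx], responses = res$responses,
        theta = res$thetaHistory, sem = res$semHistory,
        stopReason = res$stopReason, trueTheta = simulees[i, ],
        ageGroup = ageGroups[i]
      )
    }
  }

  new("SimulationSummary",
    itemCounts = counts, stopReasons = reasons,
    itemCountStats = itemCountStats(counts, J),
    reliabilityStats = reliabilityStatsMatrix(rel),
    terminalReliability = rel,
    rule = rule, sessions = sessions
  )
}

#' Starting-item regression
#'
#' Ordinary least squares for the influence of the starting item (dummy
#' coded within age group against a per-group reference item) and the
#' stopping rule (indicator for the looser rule) on the sum of squared
#' terminal SEMs over the reported dimensions. Coefficients are reported
#' most-negative first within each age group, i.e. the most beneficial
#' starting item leads.
#'
#' @param results data.frame with columns `age_group`, `start_item`,
#'   `stop_rule` and `sss` (the summed squared SEM outcome).
#' @param referenceLevels named character vector: reference start item per
#'   age group. Defaults to the first level within each group.
#' @param looserRule value of `stop_rule` treated as the looser rule
#'   indicator (default the lexicographically last unique value).
#' @return data.frame with columns term, age_group, b, SE, t, p, beta.
#' @export
startingItemRegression <- function(results, referenceLevels = NULL,
                                   looserRule = NULL) {
  req <- c("age_group", "start_item", "stop_rule", "sss")
  if (!all(req %in% names(results)))
    stop("results must have columns ", paste(req, collapse = ", "))
  if (any(!is.finite(results$sss))) stop("outcome must be finite")
  results$age_group <- as.character(results$age_group)
  results$start_item <- as.character(results$start_item)
  groups <- sort(unique(results$age_group))
  if (is.null(referenceLevels)) {
    referenceLevels <- vapply(groups, function(g)
      sort(unique(results$start_item[results$age_group == g]))[1],
      character(1))
  }
  rules <- sort(unique(as.character(results$stop_rule)))
  if (length(rules) < 2L && is.null(looserRule))
    looserRule <- rules[1]
  looserRule <- looserRule %||% rules[length(rules)]

  ## design: intercept + looser-rule indicator + per-group start-item dummies
  X <- list(stop_rule = as.numeric(results$stop_rule == looserRule))
  meta <- data.frame(term = "stop_rule", age_group = "",
                     stringsAsFactors = FALSE)
  for (g in groups) {
    lev <- sort(unique(results$start_item[results$age_group == g]))
    lev <- setdiff(lev, referenceLevels[[g]])
    if (!length(lev))
      stop("age group ", g, " needs at least 2 start-item levels")
    for (it in lev) {
      nm <- paste0(g, ":", it)
      X[[nm]] <- as.numeric(results$age_group == g &
                              results$start_item == it)
      meta <- rbind(meta, data.frame(term = it, age_group = g,
                                     stringsAsFactors = FALSE))
    }
  }
  Xm <- do.call(cbind, X)
  if (qr(cbind(1, Xm))$rank < ncol(Xm) + 1L)
    stop("collinear design: start items / rules are confounded")
  df <- data.frame(sss = results$sss, Xm, check.names = FALSE)
  fit <- lm(sss ~ ., data = df)
  sm <- summary(fit)$coefficients
  sy <- sd(results$sss)
  out <- data.frame(
    term = c("(Intercept)", meta$term),
    age_group = c("", meta$age_group),
    b = sm[, 1], SE = sm[, 2], t = sm[, 3], p = sm[, 4],
    beta = c(NA, sm[-1, 1] * apply(Xm, 2, sd) / sy),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ## order start-item coefficients most-negative first within age group
  headRows <- out[out$age_group == "", ]
  itemRows <- out[out$age_group != "", ]
  itemRows <- itemRows[order(itemRows$age_group, itemRows$b), ]
  rbind(headRows, itemRows)
}

#' Summed squared SEM outcomes for the starting-item study
#'
#' Runs one session per (simulee, candidate starting item, stopping rule)
#' cell, overriding the bank's designated starting item, and returns the
#' per-session sum of squared terminal SEMs over the reported dimensions —
#' the outcome minimised when choosing starting items.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param simulees n x D matrix of true traits.
#' @param ageGroups character vector per simulee.
#' @param candidateItems named list: age-group label -> character vector of
#'   candidate starting item ids.
#' @param stopConfigs named list of \linkS4class{StopRuleConfig}s.
#' @param rule selection rule.
#' @param seed base seed.
#' @return data.frame(age_group, start_item, stop_rule, sss) ready for
#'   [startingItemRegression()].
#' @export
startingItemStudy <- function(bank, simulees, ageGroups, candidateItems,
                              stopConfigs, rule = "AP", seed = 1) {
  bm <- bankMatrices(bank)
  rd <- reportedDimensions(bank)
  w <- defaultWeights(bank, rd)
  priorMean <- rep(0, nDimensions(bank))
  rows <- list()
  for (i in seq_len(nrow(simulees))) {
    g <- as.character(ageGroups[i])
    ptrue <- bankProb(bm, simulees[i, ])$p
    u <- withSeed(seed + i, runif(length(ptrue)))
    respondFun <- function(idx, prob) as.integer(u[idx] < ptrue[idx])
    for (startId in candidateItems[[g]]) {
      sIdx <- match(startId, bm$ids)
      if (is.na(sIdx)) stop("unknown starting item: ", startId)
      for (rn in names(stopConfigs)) {
        res <- runSessionInternal(bm, sIdx, respondFun, rule,
                                  stopConfigs[[rn]], priorMean,
                                  traitCov(bank), rd, w)
        k <- length(res$adminIdx)
        rows[[length(rows) + 1L]] <- data.frame(
          age_group = g, start_item = startId, stop_rule = rn,
          sss = sum(res$semHistory[k, rd]^2), stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
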