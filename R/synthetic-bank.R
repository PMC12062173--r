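## Synthetic item banks with the statistical geometry of a calibrated
## early-literacy pool: 177 items over six correlated content scales,
## difficulty (MDIFF) spread over -2..+2, predominantly high discrimination
## (MDISC > 1.5), 4PL asymptotes, and an optional bifactor block whose items
## additionally load on uncorrelated nuisance dimensions.

.DEFAULT_SCALES <- c(
  concepts_of_print = 38L, print_awareness = 19L, word_awareness = 12L,
  phonological_awareness = 28L, alphabet_knowledge = 45L,
  early_reading = 35L
)

#' Specify a synthetic item bank
#'
#' Defaults emulate the published pool geometry: 177 items over six content
#' scales, MDIFF uniform on \eqn{[-2, 2]}, MDISC lognormal with most mass
#' above 1.5 and a minority between 0.5 and 1.5, lower asymptotes in
#' \eqn{[0, 0.3]} (four-option multiple choice), upper asymptotes in
#' \eqn{[0.85, 1]}, a common content-trait correlation of 0.75, and two
#' bifactor nuisance dimensions attached to the first half of the first
#' scale.
#'
#' @param nItemsPerScale named integer vector of items per content scale.
#' @param difficultyRange numeric length-2 MDIFF range.
#' @param mdiscMeanlog,mdiscSdlog,mdiscRange lognormal location/scale and
#'   truncation bounds for the MDISC draw.
#' @param lowerRange,upperRange asymptote ranges.
#' @param traitCorrelation common correlation among content traits.
#' @param nNuisance number of bifactor nuisance dimensions.
#' @param nuisanceBlock first/last item position (within the first scale) of
#'   the bifactor block.
#' @return A \linkS4class{BankSpec}.
#' @export
bankSpec <- function(nItemsPerScale = .DEFAULT_SCALES,
                     difficultyRange = c(-2, 2),
                     mdiscMeanlog = log(2.5), mdiscSdlog = 0.8,
                     mdiscRange = c(0.5, 12),
                     lowerRange = c(0, 0.3),
                     upperRange = c(0.85, 1),
                     traitCorrelation = 0.75,
                     nNuisance = 2L,
                     nuisanceBlock = c(1L, 20L)) {
  new("BankSpec",
    nItemsPerScale = setNames(as.integer(nItemsPerScale),
                              names(nItemsPerScale)),
    difficultyRange = difficultyRange,
    mdiscMeanlog = mdiscMeanlog, mdiscSdlog = mdiscSdlog,
    mdiscRange = mdiscRange,
    lowerRange = lowerRange, upperRange = upperRange,
    traitCorrelation = traitCorrelation,
    nNuisance = as.integer(nNuisance),
    nuisanceBlock = as.integer(nuisanceBlock)
  )
}

## Truncated lognormal draw by rejection (the truncation region carries
## nearly all mass, so this terminates quickly).
rlnormTrunc <- function(n, meanlog, sdlog, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(2L * (n - length(out)) + 8L, meanlog, sdlog)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic item bank
#'
#' Draws item parameters satisfying the spec: per-scale item counts, MDIFF
#' uniform over the difficulty range (with the endpoints pinned so the
#' generated pool always spans the full range), truncated-lognormal MDISC,
#' uniform asymptotes, compound-symmetric content-trait correlations, and a
#' bifactor block splitting its discrimination between the content and a
#' nuisance dimension. Three starting items (one easy item per age group)
#' are designated on the first scale at increasing difficulty.
#'
#' @param spec a \linkS4class{BankSpec}.
#' @param seed RNG seed; the same seed reproduces the identical bank.
#' @return An \linkS4class{ItemBank}.
#' @examples
#' b <- generateBank(bankSpec(), seed = 1)
#' length(bankItems(b))  # 177
#' @export
generateBank <- function(spec = bankSpec(), seed = NULL) {
  stopifnot(is(spec, "BankSpec"))
  withSeed(seed, {
    scales <- names(spec@nItemsPerScale)
    nScales <- length(scales)
    J <- sum(spec@nItemsPerScale)
    D <- nScales + spec@nNuisance
    dimLabels <- c(scales,
                   if (spec@nNuisance > 0L)
                     paste0("nuisance_", seq_len(spec@nNuisance)))
    nuis <- c(rep(FALSE, nScales), rep(TRUE, spec@nNuisance))

    ## content traits compound-symmetric, nuisance orthogonal
    R <- diag(D)
    R[seq_len(nScales), seq_len(nScales)] <- spec@traitCorrelation
    diag(R) <- 1

    lo <- spec@difficultyRange[1]
    hi <- spec@difficultyRange[2]
    items <- vector("list", J)
    pos <- 0L
    for (s in seq_len(nScales)) {
      n <- spec@nItemsPerScale[s]
      mdiffs <- runif(n, lo, hi)
      ## pin the first two items of each scale to the endpoints so the pool
      ## always covers the full difficulty band
      if (n >= 2L) mdiffs[1:2] <- c(lo, hi)
      mdiscs <- rlnormTrunc(n, spec@mdiscMeanlog, spec@mdiscSdlog,
                            spec@mdiscRange[1], spec@mdiscRange[2])
      chis <- runif(n, spec@lowerRange[1], spec@lowerRange[2])
      gmas <- runif(n, spec@upperRange[1], spec@upperRange[2])
      for (i in seq_len(n)) {
        pos <- pos + 1L
        a <- rep(0, D)
        inBlock <- s == 1L && spec@nNuisance > 0L &&
          i >= spec@nuisanceBlock[1] && i <= spec@nuisanceBlock[2]
        if (inBlock) {
          nd <- nScales + 1L + (i %% spec@nNuisance)
          frac <- runif(1, 0.3, 0.6)  # share of MDISC on the nuisance axis
          a[s] <- mdiscs[i] * sqrt(1 - frac^2)
          a[nd] <- mdiscs[i] * frac
        } else {
          a[s] <- mdiscs[i]
        }
        items[[pos]] <- itemParameters(
          itemId = sprintf("%s_%03d", scales[s], i),
          loadings = a,
          intercept = -mdiffs[i] * mdiscs[i],
          lowerAsymptote = chis[i],
          upperAsymptote = gmas[i],
          primaryDimension = s,
          scaleLabel = scales[s]
        )
      }
    }

    ## starting items: easy items on the first scale, slightly harder for
    ## older groups
    md <- vapply(items, function(it) -it@intercept / sqrt(sum(it@loadings^2)),
                 numeric(1))
    firstScale <- which(vapply(items, function(it) it@scaleLabel,
                               character(1)) == scales[1])
    targets <- c("4" = -1.5, "5" = -1.0, "6" = -0.5)
    startIds <- character(0)
    used <- integer(0)
    for (g in names(targets)) {
      cand <- setdiff(firstScale, used)
      pick <- cand[which.min(abs(md[cand] - targets[g]))]
      used <- c(used, pick)
      items[[pick]]@startAgeGroup <- g
      startIds[g] <- items[[pick]]@itemId
    }

    itemBank(items, dimensionLabels = dimLabels, traitCov = R,
             nuisanceDimensions = nuis, startingItems = startIds)
  })
}

#' Canonical reference fixture
#'
#' The fixture used throughout the test and acceptance harness: the default
#' synthetic bank, a simulee population drawn from the bank's trait prior,
#' and a digest of summary statistics frozen for regression testing.
#'
#' @param seed base seed; the bank uses `seed`, the simulees `seed + 1`.
#' @param nSimulees number of simulees to draw.
#' @return list(bank, simulees, digest) where digest is a named numeric
#'   vector of rounded summary statistics of the fixture.
#' @export
makeReferenceFixture <- function(seed = 1, nSimulees = 200L) {
  bank <- generateBank(bankSpec(), seed = seed)
  simulees <- generateSimulees(nSimulees, rep(0, nDimensions(bank)),
                               traitCov(bank), seed = seed + 1)
  md <- bankMdiff(bank)
  ms <- bankMdisc(bank)
  digest <- round(c(
    nItems = length(bankItems(bank)),
    meanMdiff = mean(md), sdMdiff = sd(md),
    meanMdisc = mean(ms), fracHighDisc = mean(ms > 1.5),
    meanTheta = mean(simulees), sdTheta = sd(as.numeric(simulees))
  ), 6)
  list(bank = bank, simulees = simulees, digest = digest)
}
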