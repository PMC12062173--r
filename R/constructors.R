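#' Create the parameters of a single 4PL item
#'
#' @param itemId unique identifier string.
#' @param loadings numeric slope vector over the bank's latent dimensions.
#' @param intercept numeric intercept.
#' @param lowerAsymptote lower asymptote (guessing floor) in [0, 1).
#' @param upperAsymptote upper asymptote (disengagement ceiling) in (0, 1].
#' @param primaryDimension index of the content dimension the item measures.
#' @param scaleLabel scale name.
#' @param startAgeGroup "" or the age-group label for which this is the
#'   starting item.
#' @return An \linkS4class{ItemParameters} object.
#' @examples
#' itemParameters("it1", loadings = c(1.8, 0), intercept = -0.5)
#' @export
itemParameters <- function(itemId, loadings, intercept,
                           lowerAsymptote = 0, upperAsymptote = 1,
                           primaryDimension = which.max(abs(loadings)),
                           scaleLabel = "", startAgeGroup = "") {
  new("ItemParameters",
    itemId = as.character(itemId),
    loadings = as.numeric(loadings),
    intercept = as.numeric(intercept),
    lowerAsymptote = as.numeric(lowerAsymptote),
    upperAsymptote = as.numeric(upperAsymptote),
    primaryDimension = as.integer(primaryDimension),
    scaleLabel = as.character(scaleLabel),
    startAgeGroup = as.character(startAgeGroup)
  )
}

#' Assemble an item bank
#'
#' @param items list of \linkS4class{ItemParameters}.
#' @param dimensionLabels character labels, one per latent dimension.
#' @param traitCov correlation matrix of the latent traits (unit diagonal,
#'   positive definite); defaults to the identity.
#' @param nuisanceDimensions logical per dimension; TRUE marks bifactor
#'   nuisance dimensions.
#' @param startingItems named character vector mapping age-group labels to
#'   item ids; may also be inferred from items' `startAgeGroup` fields.
#' @return An \linkS4class{ItemBank}.
#' @export
itemBank <- function(items, dimensionLabels,
                     traitCov = diag(length(dimensionLabels)),
                     nuisanceDimensions = rep(FALSE, length(dimensionLabels)),
                     startingItems = NULL) {
  D <- length(dimensionLabels)
  if (is.null(startingItems)) {
    grp <- vapply(items, function(x) x@startAgeGroup, character(1))
    ids <- vapply(items, function(x) x@itemId, character(1))
    keep <- nzchar(grp)
    startingItems <- setNames(ids[keep], grp[keep])
  }
  if (length(startingItems))
    startingItems <- startingItems[order(names(startingItems))]
  dimnames(traitCov) <- list(dimensionLabels, dimensionLabels)
  new("ItemBank",
    items = items,
    nDimensions = as.integer(D),
    dimensionLabels = as.character(dimensionLabels),
    nuisanceDimensions = as.logical(nuisanceDimensions),
    traitCov = traitCov,
    startingItems = startingItems
  )
}

#' Configure the staged stopping rule
#'
#' Defaults reproduce the staged rule used operationally: SEM below
#' \eqn{\sqrt{0.15} \approx 0.3873} (reliability 0.85) through item 49, SEM
#' below \eqn{\sqrt{0.2} \approx 0.4472} (reliability 0.80) from item 50, and
#' from item 60 the stability criterion
#' \eqn{\sum_f (\mathrm{SEM}_f^{max} - \mathrm{SEM}_f^{min})^2 < 0.0005}
#' over the last 10 items.
#'
#' @param stage1Threshold,stage2Threshold SEM thresholds for the two stages.
#' @param stage1Through last item position governed by stage 1.
#' @param stabilityStart,stabilityWindow,stabilityThreshold stability-rule
#'   parameters.
#' @param reportedDimensions integer dimension indices the thresholds apply
#'   to; empty means all content dimensions of the bank.
#' @return A \linkS4class{StopRuleConfig}.
#' @export
stopRuleConfig <- function(stage1Threshold = sqrt(0.15),
                           stage2Threshold = sqrt(0.2),
                           stage1Through = 49L,
                           stabilityStart = 60L,
                           stabilityWindow = 10L,
                           stabilityThreshold = 5e-4,
                           reportedDimensions = integer()) {
  new("StopRuleConfig",
    stage1Threshold = stage1Threshold,
    stage2Threshold = stage2Threshold,
    stage1Through = as.integer(stage1Through),
    stabilityStart = as.integer(stabilityStart),
    stabilityWindow = as.integer(stabilityWindow),
    stabilityThreshold = stabilityThreshold,
    reportedDimensions = as.integer(reportedDimensions)
  )
}

#' Single-threshold stopping rule
#'
#' Convenience wrapper for simulation runs that apply one SEM threshold on
#' every reported dimension from the first item on, with the stability rule
#' disabled: both stages share the threshold and the stability check is
#' pushed beyond any finite bank.
#'
#' @param threshold SEM threshold, e.g. `semFromReliability(0.8)`.
#' @param reportedDimensions as in [stopRuleConfig()].
#' @return A \linkS4class{StopRuleConfig}.
#' @export
semThresholdStop <- function(threshold, reportedDimensions = integer()) {
  stopRuleConfig(
    stage1Threshold = threshold, stage2Threshold = threshold,
    stage1Through = 0L, stabilityStart = .Machine$integer.max,
    reportedDimensions = reportedDimensions
  )
}

#' Specify a confirmatory MIRT model
#'
#' @param family "M2PL", "M3PL" or "M4PL".
#' @param loadingPattern items x dimensions binary matrix of free loadings.
#' @param correlatedTraits logical; estimate correlations among content
#'   traits.
#' @param nuisanceDimensions logical per dimension.
#' @return A \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(family = c("M2PL", "M3PL", "M4PL"),
                      loadingPattern,
                      correlatedTraits = FALSE,
                      nuisanceDimensions = rep(FALSE, ncol(loadingPattern))) {
  family <- match.arg(family)
  storage.mode(loadingPattern) <- "double"
  new("ModelSpec",
    family = family,
    loadingPattern = loadingPattern,
    correlatedTraits = correlatedTraits,
    nuisanceDimensions = as.logical(nuisanceDimensions)
  )
}
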