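## Accessor generics and show() methods. Slots are never reached into from
## user code; these are the supported surface.

#' @rdname ItemBank-accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))
#' @rdname ItemBank-accessors
#' @export
setGeneric("nDimensions", function(x) standardGeneric("nDimensions"))
#' @rdname ItemBank-accessors
#' @export
setGeneric("dimensionLabels", function(x) standardGeneric("dimensionLabels"))
#' @rdname ItemBank-accessors
#' @export
setGeneric("traitCov", function(x) standardGeneric("traitCov"))
#' @rdname ItemBank-accessors
#' @export
setGeneric("startingItems", function(x) standardGeneric("startingItems"))
#' @rdname ItemBank-accessors
#' @export
setGeneric("bankItems", function(x) standardGeneric("bankItems"))
#' @rdname ItemBank-accessors
#' @export
setGeneric("getItem", function(x, id) standardGeneric("getItem"))
#' @rdname ItemBank-accessors
#' @export
setGeneric("reportedDimensions", function(x) standardGeneric("reportedDimensions"))
#' @rdname ItemBank-accessors
#' @export
setGeneric("loadingMatrix", function(x) standardGeneric("loadingMatrix"))

#' Accessors for item banks
#'
#' @param x an \linkS4class{ItemBank}.
#' @param id an item id.
#' @return `itemIds` the character ids in bank order; `nDimensions` the latent
#'   dimension count; `dimensionLabels` their labels; `traitCov` the trait
#'   correlation matrix; `startingItems` the named age-group to item-id map;
#'   `bankItems` the list of \linkS4class{ItemParameters}; `getItem` one item
#'   by id; `reportedDimensions` the integer indices of the content (non
#'   nuisance) dimensions; `loadingMatrix` the items x dimensions slope
#'   matrix.
#' @name ItemBank-accessors
NULL

#' @rdname ItemBank-accessors
#' @export
setMethod("itemIds", "ItemBank", function(x)
  vapply(x@items, function(it) it@itemId, character(1)))
#' @rdname ItemBank-accessors
#' @export
setMethod("nDimensions", "ItemBank", function(x) x@nDimensions)
#' @rdname ItemBank-accessors
#' @export
setMethod("dimensionLabels", "ItemBank", function(x) x@dimensionLabels)
#' @rdname ItemBank-accessors
#' @export
setMethod("traitCov", "ItemBank", function(x) x@traitCov)
#' @rdname ItemBank-accessors
#' @export
setMethod("startingItems", "ItemBank", function(x) x@startingItems)
#' @rdname ItemBank-accessors
#' @export
setMethod("bankItems", "ItemBank", function(x) x@items)
#' @rdname ItemBank-accessors
#' @export
setMethod("getItem", "ItemBank", function(x, id) {
  pos <- match(id, itemIds(x))
  if (is.na(pos)) stop("unknown item id: ", id)
  x@items[[pos]]
})
#' @rdname ItemBank-accessors
#' @export
setMethod("reportedDimensions", "ItemBank", function(x)
  which(!x@nuisanceDimensions))
#' @rdname ItemBank-accessors
#' @export
setMethod("loadingMatrix", "ItemBank", function(x) {
  A <- t(vapply(x@items, function(it) it@loadings,
                numeric(x@nDimensions)))
  if (x@nDimensions == 1L) A <- matrix(A, ncol = 1L)
  rownames(A) <- itemIds(x)
  colnames(A) <- x@dimensionLabels
  A
})

#' @rdname AbilityEstimate-accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
#' @rdname AbilityEstimate-accessors
#' @export
setGeneric("sem", function(x) standardGeneric("sem"))
#' @rdname AbilityEstimate-accessors
#' @export
setGeneric("reliability", function(x) standardGeneric("reliability"))
#' @rdname AbilityEstimate-accessors
#' @export
setGeneric("tScores", function(x) standardGeneric("tScores"))

#' Accessors for ability estimates
#'
#' @param x an \linkS4class{AbilityEstimate}.
#' @return Named numeric vectors over dimensions: MAP `theta`, standard error
#'   `sem`, model-based `reliability` (1 − SEM²), and `tScores`
#'   (50 + 10·theta).
#' @name AbilityEstimate-accessors
NULL

#' @rdname AbilityEstimate-accessors
#' @export
setMethod("theta", "AbilityEstimate", function(x)
  setNames(x@theta, x@dimensionLabels))
#' @rdname AbilityEstimate-accessors
#' @export
setMethod("sem", "AbilityEstimate", function(x)
  setNames(x@sem, x@dimensionLabels))
#' @rdname AbilityEstimate-accessors
#' @export
setMethod("reliability", "AbilityEstimate", function(x)
  setNames(x@reliability, x@dimensionLabels))
#' @rdname AbilityEstimate-accessors
#' @export
setMethod("tScores", "AbilityEstimate", function(x)
  setNames(x@tScores, x@dimensionLabels))

#' @rdname CatSession-accessors
#' @export
setGeneric("administeredItems", function(x) standardGeneric("administeredItems"))
#' @rdname CatSession-accessors
#' @export
setGeneric("sessionResponses", function(x) standardGeneric("sessionResponses"))
#' @rdname CatSession-accessors
#' @export
setGeneric("estimateHistory", function(x) standardGeneric("estimateHistory"))
#' @rdname CatSession-accessors
#' @export
setGeneric("isStopped", function(x) standardGeneric("isStopped"))
#' @rdname CatSession-accessors
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))
#' @rdname CatSession-accessors
#' @export
setGeneric("currentEstimate", function(x) standardGeneric("currentEstimate"))

#' Accessors for CAT sessions
#'
#' @param x a \linkS4class{CatSession}.
#' @return `administeredItems` the ordered item ids; `sessionResponses` the
#'   0/1 responses; `estimateHistory` a list with `theta` and `sem` matrices
#'   (one row per administered item); `isStopped`/`stopReason` the stop
#'   status; `currentEstimate` the latest \linkS4class{AbilityEstimate}.
#' @name CatSession-accessors
NULL

#' @rdname CatSession-accessors
#' @export
setMethod("administeredItems", "CatSession", function(x) x@administered)
#' @rdname CatSession-accessors
#' @export
setMethod("sessionResponses", "CatSession", function(x) x@responses)
#' @rdname CatSession-accessors
#' @export
setMethod("estimateHistory", "CatSession", function(x)
  list(theta = x@thetaHistory, sem = x@semHistory))
#' @rdname CatSession-accessors
#' @export
setMethod("isStopped", "CatSession", function(x) x@stopped)
#' @rdname CatSession-accessors
#' @export
setMethod("stopReason", "CatSession", function(x) x@stopReason)
#' @rdname CatSession-accessors
#' @export
setMethod("currentEstimate", "CatSession", function(x) {
  k <- length(x@administered)
  mapEstimate(x@bank, x@administered, x@responses, priorMean = x@priorMean)
})

setMethod("show", "ItemParameters", function(object) {
  cat("ItemParameters \"", object@itemId, "\" (scale ", object@scaleLabel,
      ")\n", sep = "")
  cat("  loadings:", paste(signif(object@loadings, 4), collapse = " "), "\n")
  cat("  intercept:", signif(object@intercept, 4),
      " asymptotes: [", signif(object@lowerAsymptote, 3), ", ",
      signif(object@upperAsymptote, 3), "]\n", sep = "")
})

setMethod("show", "ItemBank", function(object) {
  cat("ItemBank with", length(object@items), "items over",
      object@nDimensions, "dimensions\n")
  cont <- which(!object@nuisanceDimensions)
  cat("  content dimensions:",
      paste(object@dimensionLabels[cont], collapse = ", "), "\n")
  if (any(object@nuisanceDimensions))
    cat("  nuisance dimensions:",
        paste(object@dimensionLabels[object@nuisanceDimensions],
              collapse = ", "), "\n")
  if (length(object@startingItems))
    cat("  starting items:",
        paste(names(object@startingItems), object@startingItems,
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "AbilityEstimate", function(object) {
  cat("AbilityEstimate (MAP)\n")
  m <- rbind(theta = object@theta, sem = object@sem,
             reliability = object@reliability, T = object@tScores)
  colnames(m) <- object@dimensionLabels
  print(round(m, 3))
})

setMethod("show", "CatSession", function(object) {
  k <- length(object@administered)
  cat("CatSession:", k, "items administered; ",
      if (object@stopped) paste0("stopped (", object@stopReason, ")")
      else "running", "\n")
})

setMethod("show", "FitIndices", function(object) {
  cat("FitIndices", if (nzchar(object@label)) paste0("[", object@label, "]"),
      "\n")
  cat(sprintf("  M2 = %.2f on df = %d, p = %.3g\n",
              object@m2, as.integer(object@df), object@p))
  cat(sprintf("  RMSEA = %.4f [%.4f, %.4f]  SRMSR = %.4f\n",
              object@rmsea, object@rmseaCI[1], object@rmseaCI[2],
              object@srmsr))
  cat(sprintf("  TLI = %.4f  CFI = %.4f  logLik = %.1f\n",
              object@tli, object@cfi, object@logLik))
})

setMethod("show", "CalibrationFit", function(object) {
  cat("CalibrationFit:", object@spec@family, "on",
      length(object@bank@items), "items,", object@nObs, "respondents\n")
  cat(sprintf("  logLik = %.2f over %d start(s)%s\n", object@logLik,
              length(object@startLogLiks),
              if (object@converged) "" else " (not converged)"))
  if (length(object@removedItems))
    cat("  removed items:", paste(object@removedItems, collapse = ", "), "\n")
})

setMethod("show", "SimulationSummary", function(object) {
  cat("SimulationSummary:", length(object@itemCounts), "simulees, rule",
      object@rule, "\n")
  print(round(object@itemCountStats, 2))
})

setMethod("show", "TrafficLightReport", function(object) {
  cat("TrafficLightReport", if (nzchar(object@childId))
    paste0("(child ", object@childId, ")"), "\n")
  df <- data.frame(T = round(object@tScores, 1),
                   category = object@categories)
  print(df)
})
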