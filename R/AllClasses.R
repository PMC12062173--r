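#' @import methods
NULL

#' Parameters of a single 4PL item
#'
#' Holds one item of a multidimensional four-parameter logistic (4PL) model in
#' slope--intercept form. The probability of a correct response at trait vector
#' \eqn{\theta} is
#' \deqn{P(\theta) = \chi + (\gamma - \chi)\,\mathrm{logistic}(a^\top\theta + d),}
#' where \eqn{a} are the loadings (discrimination slopes), \eqn{d} the
#' intercept, \eqn{\chi} the lower asymptote (guessing) and \eqn{\gamma} the
#' upper asymptote (disengagement/slipping). The curve is compressed in the
#' y-direction so that it stays within \eqn{[\chi, \gamma]} for every ability
#' level.
#'
#' @slot itemId character identifier, unique within a bank.
#' @slot loadings numeric vector of slopes, one per latent dimension of the
#'   owning bank; confirmatory structure means most entries are zero.
#' @slot intercept numeric intercept \eqn{d}.
#' @slot lowerAsymptote lower bound \eqn{\chi} in \eqn{[0, 1)}.
#' @slot upperAsymptote upper bound \eqn{\gamma} in \eqn{(0, 1]};
#'   \eqn{\chi < \gamma} is enforced.
#' @slot primaryDimension integer index of the content dimension the item
#'   primarily measures.
#' @slot scaleLabel character label of the scale the item belongs to.
#' @slot startAgeGroup character; "" or one of the age-group labels for which
#'   the item serves as the fixed starting item.
#' @export
setClass("ItemParameters",
  representation(
    itemId = "character",
    loadings = "numeric",
    intercept = "numeric",
    lowerAsymptote = "numeric",
    upperAsymptote = "numeric",
    primaryDimension = "integer",
    scaleLabel = "character",
    startAgeGroup = "character"
  ),
  prototype(
    lowerAsymptote = 0, upperAsymptote = 1,
    primaryDimension = 1L, scaleLabel = "", startAgeGroup = ""
  )
)

setValidity("ItemParameters", function(object) {
  msg <- character()
  if (length(object@itemId) != 1L || !nzchar(object@itemId))
    msg <- c(msg, "itemId must be a single non-empty string")
  if (length(object@loadings) < 1L || any(!is.finite(object@loadings)))
    msg <- c(msg, "loadings must be a non-empty finite numeric vector")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  chi <- object@lowerAsymptote
  gma <- object@upperAsymptote
  if (length(chi) != 1L || chi < 0 || chi >= 1)
    msg <- c(msg, "lowerAsymptote must lie in [0, 1)")
  if (length(gma) != 1L || gma <= 0 || gma > 1)
    msg <- c(msg, "upperAsymptote must lie in (0, 1]")
  if (length(chi) == 1L && length(gma) == 1L && !(chi < gma))
    msg <- c(msg, "lowerAsymptote must be strictly below upperAsymptote")
  pd <- object@primaryDimension
  if (length(pd) != 1L || is.na(pd) || pd < 1L ||
      pd > length(object@loadings))
    msg <- c(msg, "primaryDimension must index into loadings")
  if (length(msg)) msg else TRUE
})

#' An ordered bank of calibrated items
#'
#' The central container for a calibrated item pool: an ordered list of
#' \linkS4class{ItemParameters}, the latent dimensionality, the labels and
#' roles (content vs. bifactor nuisance) of the dimensions, the trait
#' correlation matrix used as the scoring prior, and the designated starting
#' items per age group.
#'
#' @slot items list of \linkS4class{ItemParameters}.
#' @slot nDimensions integer latent dimension count D.
#' @slot dimensionLabels character vector of length D.
#' @slot nuisanceDimensions logical vector of length D; TRUE marks bifactor
#'   nuisance dimensions that are estimated but not reported.
#' @slot traitCov D x D symmetric positive-definite matrix with unit diagonal
#'   (a correlation matrix) describing the correlated traits.
#' @slot startingItems named character vector mapping age-group labels
#'   (e.g. "4", "5", "6") to item ids.
#' @export
setClass("ItemBank",
  representation(
    items = "list",
    nDimensions = "integer",
    dimensionLabels = "character",
    nuisanceDimensions = "logical",
    traitCov = "matrix",
    startingItems = "character"
  )
)

setValidity("ItemBank", function(object) {
  msg <- character()
  D <- object@nDimensions
  if (length(D) != 1L || D < 1L)
    return("nDimensions must be a positive integer")
  if (!all(vapply(object@items, is, logical(1), "ItemParameters")))
    msg <- c(msg, "items must all be ItemParameters objects")
  ids <- vapply(object@items, function(x) x@itemId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "item ids must be unique")
  lens <- vapply(object@items, function(x) length(x@loadings), integer(1))
  if (length(lens) && any(lens != D))
    msg <- c(msg, "every item's loadings must have length nDimensions")
  prim <- vapply(object@items, function(x) x@primaryDimension, integer(1))
  if (length(prim) && any(prim > D))
    msg <- c(msg, "every item's primaryDimension must be < nDimensions")
  if (length(object@dimensionLabels) != D)
    msg <- c(msg, "dimensionLabels must have length nDimensions")
  if (length(object@nuisanceDimensions) != D)
    msg <- c(msg, "nuisanceDimensions must have length nDimensions")
  if (!isSquareSymmetric(object@traitCov) || nrow(object@traitCov) != D)
    msg <- c(msg, "traitCov must be a D x D symmetric matrix")
  else {
    if (max(abs(diag(object@traitCov) - 1)) > 1e-8)
      msg <- c(msg, "traitCov must have unit diagonal (correlation matrix)")
    if (!isPositiveDefinite(object@traitCov))
      msg <- c(msg, "traitCov must be positive definite")
  }
  if (length(object@startingItems)) {
    if (is.null(names(object@startingItems)) ||
        any(!nzchar(names(object@startingItems))))
      msg <- c(msg, "startingItems must be a named character vector")
    if (!all(object@startingItems %in% ids))
      msg <- c(msg, "startingItems must refer to item ids in the bank")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a confirmatory MIRT model
#'
#' Describes which model family (M2PL/M3PL/M4PL), which confirmatory loading
#' pattern (items x dimensions, including bifactor nuisance columns), and
#' whether the content traits are correlated. M2PL fixes
#' \eqn{\chi = 0, \gamma = 1}; M3PL additionally frees the lower asymptotes;
#' M4PL frees both asymptotes, so the families are nested.
#'
#' @slot family one of "M2PL", "M3PL", "M4PL".
#' @slot loadingPattern items x dimensions binary matrix; 1 marks a free
#'   loading.
#' @slot correlatedTraits logical; free correlations among content traits.
#' @slot nuisanceDimensions logical vector over dimensions; nuisance
#'   dimensions stay uncorrelated with everything.
#' @export
setClass("ModelSpec",
  representation(
    family = "character",
    loadingPattern = "matrix",
    correlatedTraits = "logical",
    nuisanceDimensions = "logical"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!(length(object@family) == 1L &&
        object@family %in% c("M2PL", "M3PL", "M4PL")))
    msg <- c(msg, "family must be one of M2PL, M3PL, M4PL")
  lp <- object@loadingPattern
  if (!is.matrix(lp) || !all(lp %in% c(0, 1)))
    msg <- c(msg, "loadingPattern must be a binary items x dimensions matrix")
  if (is.matrix(lp) && any(rowSums(lp) < 1))
    msg <- c(msg, "every item must load on at least one dimension")
  if (length(object@nuisanceDimensions) != ncol(lp))
    msg <- c(msg, "nuisanceDimensions must have one entry per dimension")
  if (length(msg)) msg else TRUE
})

#' Limited-information fit indices for a calibrated model
#'
#' Container for the M2 statistic on first- and second-order margins and the
#' derived indices: degrees of freedom, p-value, RMSEA with a 90%-style
#' confidence interval, SRMSR, TLI and CFI, together with the marginal
#' log-likelihood and bookkeeping counts.
#'
#' @slot m2,df,p,rmsea,srmsr,tli,cfi,logLik numeric scalars.
#' @slot rmseaCI numeric length-2 lower/upper confidence bounds for RMSEA.
#' @slot nObs,nParameters integer sample size and free-parameter count.
#' @slot label character tag used in comparison tables.
#' @export
setClass("FitIndices",
  representation(
    m2 = "numeric", df = "numeric", p = "numeric",
    rmsea = "numeric", rmseaCI = "numeric", srmsr = "numeric",
    tli = "numeric", cfi = "numeric", logLik = "numeric",
    nObs = "integer", nParameters = "integer", label = "character"
  ),
  prototype(label = "")
)

setValidity("FitIndices", function(object) {
  msg <- character()
  if (length(object@df) == 1L && is.finite(object@df) && object@df < 0)
    msg <- c(msg, "df must be nonnegative")
  if (length(object@rmsea) == 1L && is.finite(object@rmsea) &&
      object@rmsea < 0)
    msg <- c(msg, "rmsea must be nonnegative")
  if (length(object@srmsr) == 1L && is.finite(object@srmsr) &&
      object@srmsr < 0)
    msg <- c(msg, "srmsr must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' A calibrated model fit
#'
#' Result of [fitMirt()]: the calibrated \linkS4class{ItemBank}, the model
#' specification, the best marginal log-likelihood over the random starts,
#' per-start log-likelihoods, and any items flagged for removal.
#'
#' @slot bank calibrated \linkS4class{ItemBank}.
#' @slot spec the \linkS4class{ModelSpec} that was fitted.
#' @slot logLik best marginal log-likelihood.
#' @slot startLogLiks numeric vector, one entry per start.
#' @slot removedItems character ids of items excluded before estimation
#'   (zero-variance / degenerate items).
#' @slot converged logical, convergence of the selected start.
#' @slot nObs integer number of respondents.
#' @export
setClass("CalibrationFit",
  representation(
    bank = "ItemBank",
    spec = "ModelSpec",
    logLik = "numeric",
    startLogLiks = "numeric",
    removedItems = "character",
    converged = "logical",
    nObs = "integer"
  )
)

#' MAP ability estimate with per-dimension precision
#'
#' The maximum a posteriori trait vector together with per-dimension standard
#' errors of measurement (SEM), model-based reliabilities
#' \eqn{Rel = 1 - SEM^2}, and T-scores \eqn{T = 50 + 10\theta}.
#'
#' @slot theta numeric MAP trait vector.
#' @slot sem numeric per-dimension standard errors.
#' @slot reliability numeric per-dimension reliabilities, \eqn{1 - SEM^2}.
#' @slot tScores numeric per-dimension T-scores.
#' @slot dimensionLabels character labels.
#' @slot reported logical; which dimensions are content (reported) dimensions.
#' @export
setClass("AbilityEstimate",
  representation(
    theta = "numeric",
    sem = "numeric",
    reliability = "numeric",
    tScores = "numeric",
    dimensionLabels = "character",
    reported = "logical"
  )
)

setValidity("AbilityEstimate", function(object) {
  msg <- character()
  n <- length(object@theta)
  if (length(object@sem) != n || length(object@reliability) != n ||
      length(object@tScores) != n)
    msg <- c(msg, "theta, sem, reliability and tScores must share a length")
  if (any(object@sem <= 0))
    msg <- c(msg, "sem must be strictly positive")
  if (max(abs(object@reliability - (1 - object@sem^2))) > 1e-8)
    msg <- c(msg, "reliability must equal 1 - sem^2 elementwise")
  if (any(object@reliability >= 1))
    msg <- c(msg, "reliability must be < 1")
  if (length(msg)) msg else TRUE
})

#' Staged stopping-rule configuration
#'
#' The staged SEM stopping rule: through item `stage1Through` (default 49) the
#' session stops once every reported dimension has SEM below
#' `stage1Threshold`; from the next item on the looser `stage2Threshold`
#' applies; and from item `stabilityStart` on, the session additionally stops
#' when the sum over reported dimensions of the squared SEM ranges over the
#' last `stabilityWindow` items falls below `stabilityThreshold` (standard
#' errors have stabilised and further items cannot reduce them meaningfully).
#'
#' @slot stage1Threshold,stage2Threshold numeric SEM thresholds; defaults
#'   \eqn{\sqrt{0.15} = 0.387298\ldots} (reliability 0.85) and
#'   \eqn{\sqrt{0.2} = 0.447213\ldots} (reliability 0.80).
#' @slot stage1Through integer last item position at which stage 1 applies.
#' @slot stabilityStart integer item position from which the stability rule is
#'   checked (default 60).
#' @slot stabilityWindow integer window length (default 10 items).
#' @slot stabilityThreshold numeric (default 0.0005).
#' @slot reportedDimensions integer indices of the dimensions the thresholds
#'   apply to; 0-length means "all content dimensions of the bank".
#' @export
setClass("StopRuleConfig",
  representation(
    stage1Threshold = "numeric",
    stage2Threshold = "numeric",
    stage1Through = "integer",
    stabilityStart = "integer",
    stabilityWindow = "integer",
    stabilityThreshold = "numeric",
    reportedDimensions = "integer"
  ),
  prototype(
    stage1Threshold = sqrt(0.15),
    stage2Threshold = sqrt(0.2),
    stage1Through = 49L,
    stabilityStart = 60L,
    stabilityWindow = 10L,
    stabilityThreshold = 5e-4,
    reportedDimensions = integer()
  )
)

setValidity("StopRuleConfig", function(object) {
  msg <- character()
  if (!(object@stage1Threshold <= object@stage2Threshold))
    msg <- c(msg, "stage1Threshold must be <= stage2Threshold")
  if (object@stage1Threshold <= 0)
    msg <- c(msg, "thresholds must be positive")
  if (object@stabilityWindow < 2L)
    msg <- c(msg, "stabilityWindow must be at least 2")
  if (object@stabilityThreshold <= 0)
    msg <- c(msg, "stabilityThreshold must be positive")
  if (length(msg)) msg else TRUE
})

#' An adaptive testing session
#'
#' State of one CAT session: the bank, the examinee's age group, the ordered
#' administered items with their scored responses, the trajectory of MAP
#' estimates and SEMs (one row per administered item), and the stop status.
#'
#' @slot bank \linkS4class{ItemBank}.
#' @slot ageGroup character age-group label.
#' @slot administered character vector of administered item ids, in order.
#' @slot responses integer 0/1 vector, parallel to `administered`.
#' @slot thetaHistory,semHistory numeric matrices, one row per administered
#'   item, one column per dimension.
#' @slot rule character selection rule.
#' @slot stopConfig \linkS4class{StopRuleConfig}.
#' @slot priorMean numeric prior mean.
#' @slot stopped logical.
#' @slot stopReason one of "", "stage1_sem", "stage2_sem", "stability",
#'   "bank_exhausted".
#' @export
setClass("CatSession",
  representation(
    bank = "ItemBank",
    ageGroup = "character",
    administered = "character",
    responses = "integer",
    thetaHistory = "matrix",
    semHistory = "matrix",
    rule = "character",
    stopConfig = "StopRuleConfig",
    priorMean = "numeric",
    stopped = "logical",
    stopReason = "character"
  ),
  prototype(stopped = FALSE, stopReason = "")
)

setValidity("CatSession", function(object) {
  msg <- character()
  if (anyDuplicated(object@administered))
    msg <- c(msg, "administered items must be unique")
  if (length(object@responses) != length(object@administered))
    msg <- c(msg, "responses must be parallel to administered")
  if (length(object@administered) &&
      nrow(object@thetaHistory) != length(object@administered))
    msg <- c(msg, "thetaHistory must have one row per administered item")
  if (object@stopped && !nzchar(object@stopReason))
    msg <- c(msg, "a stopped session must carry a stopReason")
  if (length(msg)) msg else TRUE
})

#' Specification for a synthetic item bank
#'
#' Parameters of the synthetic bank generator, chosen to emulate the geometry
#' of a calibrated early-literacy pool: six content scales totalling 177
#' items, multidimensional difficulty (MDIFF) spread over −2..+2,
#' predominantly high multidimensional discrimination (MDISC > 1.5), 4PL
#' asymptotes, correlated content traits, and an optional block of bifactor
#' items loading on extra nuisance dimensions.
#'
#' @slot nItemsPerScale named integer vector, items per content scale.
#' @slot difficultyRange numeric length-2 MDIFF range.
#' @slot mdiscMeanlog,mdiscSdlog lognormal parameters of the MDISC draw.
#' @slot mdiscRange numeric length-2 truncation bounds for MDISC.
#' @slot lowerRange,upperRange numeric length-2 ranges for the asymptotes.
#' @slot traitCorrelation numeric common correlation among content traits.
#' @slot nNuisance integer number of bifactor nuisance dimensions.
#' @slot nuisanceBlock integer length-2: first/last item position (within the
#'   first scale) of the bifactor block.
#' @export
setClass("BankSpec",
  representation(
    nItemsPerScale = "integer",
    difficultyRange = "numeric",
    mdiscMeanlog = "numeric",
    mdiscSdlog = "numeric",
    mdiscRange = "numeric",
    lowerRange = "numeric",
    upperRange = "numeric",
    traitCorrelation = "numeric",
    nNuisance = "integer",
    nuisanceBlock = "integer"
  )
)

setValidity("BankSpec", function(object) {
  msg <- character()
  if (any(object@nItemsPerScale < 1L))
    msg <- c(msg, "every scale needs at least one item")
  if (is.null(names(object@nItemsPerScale)))
    msg <- c(msg, "nItemsPerScale must be named by scale")
  if (diff(object@difficultyRange) <= 0)
    msg <- c(msg, "difficultyRange must be increasing")
  if (object@lowerRange[1] < 0 || object@lowerRange[2] >= 1)
    msg <- c(msg, "lowerRange must lie in [0, 1)")
  if (object@upperRange[1] <= object@lowerRange[2])
    msg <- c(msg, "upperRange must lie above lowerRange")
  if (object@traitCorrelation < 0 || object@traitCorrelation >= 1)
    msg <- c(msg, "traitCorrelation must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Summary of a Monte Carlo CAT simulation
#'
#' Per-simulee item counts and terminal reliabilities, plus the aggregate
#' statistic set used to compare selection and stopping rules: mean, SD, min,
#' median, upper percentiles and the fraction of simulees using the full
#' bank; and per-dimension reliability statistics at termination.
#'
#' @slot itemCounts integer vector, items administered per simulee.
#' @slot stopReasons character vector, parallel to `itemCounts`.
#' @slot itemCountStats named numeric vector of aggregate count statistics.
#' @slot reliabilityStats numeric matrix, statistics x reported dimensions.
#' @slot terminalReliability numeric matrix, simulees x reported dimensions.
#' @slot rule character selection rule used.
#' @slot sessions list of per-simulee session logs (may be empty when
#'   streaming was disabled).
#' @export
setClass("SimulationSummary",
  representation(
    itemCounts = "integer",
    stopReasons = "character",
    itemCountStats = "numeric",
    reliabilityStats = "matrix",
    terminalReliability = "matrix",
    rule = "character",
    sessions = "list"
  )
)

#' Traffic-light screening report
#'
#' Per-scale T-scores classified into the three screening categories:
#' "red" (at risk), "orange" (monitoring needed) and "green" (on track).
#' Classification is a deterministic function of the T-score and the two
#' cut-offs: T below `redBelow` is red, T in [redBelow, orangeBelow) is
#' orange, anything else green.
#'
#' @slot tScores named numeric per-scale T-scores.
#' @slot categories named character, one of "red", "orange", "green".
#' @slot thresholds numeric length-2, c(redBelow, orangeBelow).
#' @slot childId,ageGroup character metadata passed through.
#' @export
setClass("TrafficLightReport",
  representation(
    tScores = "numeric",
    categories = "character",
    thresholds = "numeric",
    childId = "character",
    ageGroup = "character"
  )
)

setValidity("TrafficLightReport", function(object) {
  if (object@thresholds[1] >= object@thresholds[2])
    return("red threshold must be below the orange threshold")
  TRUE
})
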