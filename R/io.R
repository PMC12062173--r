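## Formats and reporting: bank CSV/JSON, response CSV, session JSONL,
## summary CSV, YAML session configuration, and the traffic-light report.

bankToFrame <- function(bank) {
  bm <- bankMatrices(bank)
  D <- bm$D
  A <- bm$A
  colnames(A) <- paste0("a_", seq_len(D))
  start <- vapply(bank@items, function(it) it@startAgeGroup, character(1))
  data.frame(
    item_id = bm$ids,
    scale_label = vapply(bank@items, function(it) it@scaleLabel,
                         character(1)),
    primary_dimension = bm$primary,
    A,
    d = bm$d, lower = bm$lo, upper = bm$up,
    start_age_group = start,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

frameToBank <- function(df, dimensionLabels = NULL, traitCov = NULL,
                        nuisanceDimensions = NULL, path = "<data>") {
  req <- c("item_id", "scale_label", "primary_dimension", "d")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  aCols <- grep("^a_[0-9]+$", names(df), value = TRUE)
  if (!length(aCols)) stop(path, ": no loading columns a_1..a_D found")
  aCols <- aCols[order(as.integer(sub("a_", "", aCols)))]
  D <- length(aCols)
  if (nrow(df) == 0L) stop(path, ": empty bank file")
  if (anyDuplicated(df$item_id))
    stop(path, ": duplicate item ids: ",
         paste(unique(df$item_id[duplicated(df$item_id)]), collapse = ", "))
  if (is.null(df$lower)) df$lower <- 0       # missing asymptotes: 2PL
  if (is.null(df$upper)) df$upper <- 1
  df$lower[is.na(df$lower)] <- 0
  df$upper[is.na(df$upper)] <- 1
  if (is.null(df$start_age_group)) df$start_age_group <- ""
  df$start_age_group[is.na(df$start_age_group)] <- ""
  items <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      itemParameters(
        itemId = df$item_id[i],
        loadings = as.numeric(df[i, aCols]),
        intercept = df$d[i],
        lowerAsymptote = df$lower[i],
        upperAsymptote = df$upper[i],
        primaryDimension = df$primary_dimension[i],
        scaleLabel = df$scale_label[i],
        startAgeGroup = as.character(df$start_age_group[i])
      ),
      error = function(e) stop(path, ", row ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  dimensionLabels <- dimensionLabels %||% paste0("dim", seq_len(D))
  itemBank(items, dimensionLabels = dimensionLabels,
           traitCov = traitCov %||% diag(D),
           nuisanceDimensions = nuisanceDimensions %||% rep(FALSE, D))
}

#' Read and write item banks
#'
#' Banks round-trip through two formats chosen by file extension: CSV
#' (columns item_id, scale_label, primary_dimension, a_1..a_D, d, lower,
#' upper, start_age_group; missing asymptotes default to the 2PL values 0
#' and 1; bank-level metadata such as the trait correlation matrix can be
#' supplied via arguments) and JSON (full fidelity including dimension
#' labels, nuisance flags and the trait covariance).
#'
#' @param path file path; ".json" selects JSON, anything else CSV.
#' @param bank an \linkS4class{ItemBank} (for writing).
#' @param dimensionLabels,traitCov,nuisanceDimensions optional bank-level
#'   metadata when reading CSV.
#' @return `readBank` an \linkS4class{ItemBank}; `writeBank` the path,
#'   invisibly.
#' @export
readBank <- function(path, dimensionLabels = NULL, traitCov = NULL,
                     nuisanceDimensions = NULL) {
  if (!file.exists(path)) stop("bank file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(js$items, stringsAsFactors = FALSE)
    tc <- if (!is.null(js$trait_covariance))
      matrix(unlist(js$trait_covariance), js$n_dimensions,
             js$n_dimensions) else NULL
    bank <- frameToBank(df,
                        dimensionLabels = js$dimension_labels,
                        traitCov = tc,
                        nuisanceDimensions = as.logical(js$nuisance_dimensions),
                        path = path)
    return(bank)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = c("NA", ""))
  frameToBank(df, dimensionLabels, traitCov, nuisanceDimensions, path)
}

#' @rdname readBank
#' @export
writeBank <- function(bank, path) {
  df <- bankToFrame(bank)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      n_dimensions = nDimensions(bank),
      dimension_labels = dimensionLabels(bank),
      nuisance_dimensions = bank@nuisanceDimensions,
      trait_covariance = unname(traitCov(bank)),
      items = df
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a response matrix
#'
#' CSV with a `respondent_id` column and one 0/1 column per item; empty
#' cells are missing. Non-binary cells are reported with their row and
#' column.
#'
#' @param path CSV path.
#' @return Numeric N x J matrix (0/1/NA) with respondent ids as row names
#'   and item ids as column names.
#' @export
readResponses <- function(path) {
  if (!file.exists(path)) stop("response file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""))
  if (!"respondent_id" %in% names(df))
    stop(path, ": missing respondent_id column")
  ids <- as.character(df$respondent_id)
  if (anyDuplicated(ids))
    stop(path, ": duplicate respondent ids")
  m <- as.matrix(df[, setdiff(names(df), "respondent_id"), drop = FALSE])
  storage.mode(m) <- "double"
  badCell <- which(!is.na(m) & !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(badCell))
    stop(sprintf("%s: non-binary response at row %d, column \"%s\"",
                 path, badCell[1, 1],
                 colnames(m)[badCell[1, 2]]))
  rownames(m) <- ids
  m
}

#' Write a session log as JSON lines
#'
#' One record per administered item: position, item id, response, the MAP
#' estimate and SEM per dimension, and the stop status after that item.
#'
#' @param session a \linkS4class{CatSession}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSessionLog <- function(session, path) {
  k <- length(session@administered)
  con <- file(path, open = "wt")
  on.exit(close(con))
  labs <- dimensionLabels(session@bank)
  for (i in seq_len(k)) {
    rec <- list(
      position = i,
      item_id = session@administered[i],
      response = session@responses[i],
      theta = setNames(as.list(session@thetaHistory[i, ]), labs),
      sem = setNames(as.list(session@semHistory[i, ]), labs),
      stopped = i == k && session@stopped,
      stop_reason = if (i == k) session@stopReason else ""
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write a simulation summary as CSV
#'
#' One row per statistic: the item-count block first, then per-dimension
#' reliability statistics.
#'
#' @param summary a \linkS4class{SimulationSummary}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSummary <- function(summary, path) {
  ic <- summary@itemCountStats
  top <- data.frame(block = "item_counts", statistic = names(ic),
                    dimension = "", value = unname(ic),
                    stringsAsFactors = FALSE)
  rs <- summary@reliabilityStats
  rel <- do.call(rbind, lapply(rownames(rs), function(dim) {
    data.frame(block = "reliability", statistic = colnames(rs),
               dimension = dim, value = unname(rs[dim, ]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rbind(top, rel), path, row.names = FALSE)
  invisible(path)
}

#' Classify per-scale T-scores into traffic-light categories
#'
#' T below `redBelow` is "red" (at risk); T in [`redBelow`, `orangeBelow`)
#' is "orange" (monitoring needed); otherwise "green" (on track). Default
#' cut-offs T < 40 (about the bottom 16% of the T-metric) and T < 45 are a
#' package convention and fully configurable.
#'
#' @param tScores named numeric per-scale T-scores.
#' @param thresholds numeric length-2 c(redBelow, orangeBelow),
#'   redBelow < orangeBelow.
#' @param childId,ageGroup metadata passed through to the report.
#' @return A \linkS4class{TrafficLightReport}.
#' @examples
#' classifyTrafficLight(c(reading = 30, phonology = 55))
#' @export
classifyTrafficLight <- function(tScores, thresholds = c(40, 45),
                                 childId = "", ageGroup = "") {
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2])
    stop("thresholds must be c(redBelow, orangeBelow) with ",
         "redBelow < orangeBelow")
  cats <- ifelse(tScores < thresholds[1], "red",
                 ifelse(tScores < thresholds[2], "orange", "green"))
  new("TrafficLightReport",
    tScores = tScores, categories = setNames(cats, names(tScores)),
    thresholds = thresholds,
    childId = as.character(childId), ageGroup = as.character(ageGroup)
  )
}

#' Write a traffic-light report as JSON
#'
#' @param report a \linkS4class{TrafficLightReport}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeReport <- function(report, path) {
  payload <- list(
    child = list(id = report@childId, age_group = report@ageGroup),
    thresholds = list(red_below = report@thresholds[1],
                      orange_below = report@thresholds[2]),
    scales = lapply(seq_along(report@tScores), function(i) {
      list(scale = names(report@tScores)[i],
           t_score = unname(report@tScores[i]),
           category = unname(report@categories[i]))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a calibration report as JSON
#'
#' Per-item parameters, per-start log-likelihoods, removed items, and
#' (optionally) fit indices.
#'
#' @param fit a \linkS4class{CalibrationFit}.
#' @param path output path.
#' @param indices optional \linkS4class{FitIndices}.
#' @return The path, invisibly.
#' @export
writeCalibrationReport <- function(fit, path, indices = NULL) {
  payload <- list(
    family = fit@spec@family,
    n_obs = fit@nObs,
    log_lik = fit@logLik,
    start_log_liks = fit@startLogLiks,
    removed_items = fit@removedItems,
    items = bankToFrame(fit@bank),
    trait_covariance = unname(traitCov(fit@bank))
  )
  if (!is.null(indices)) {
    payload$fit_indices <- list(
      m2 = indices@m2, df = indices@df, p = indices@p,
      rmsea = indices@rmsea, rmsea_ci = indices@rmseaCI,
      srmsr = indices@srmsr, tli = indices@tli, cfi = indices@cfi
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a session configuration
#'
#' YAML with optional sections `model`, `cat`, `stop`, `simulation` and
#' `report`; recognised `stop` keys map onto [stopRuleConfig()] fields.
#'
#' @param path YAML path.
#' @return list(rule, stopConfig, raw) where `raw` is the full parsed
#'   config.
#' @export
readCatConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  stop <- cfg$stop %||% list()
  sc <- stopRuleConfig(
    stage1Threshold = stop$stage1_threshold %||% sqrt(0.15),
    stage2Threshold = stop$stage2_threshold %||% sqrt(0.2),
    stage1Through = stop$stage1_through %||% 49L,
    stabilityStart = stop$stability_start %||% 60L,
    stabilityWindow = stop$stability_window %||% 10L,
    stabilityThreshold = stop$stability_threshold %||% 5e-4
  )
  list(rule = (cfg$cat %||% list())$rule %||% "AP",
       stopConfig = sc, raw = cfg)
}
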