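## Core 4PL response model: probabilities, Fisher information, and Reckase
## multidimensional difficulty/discrimination summaries.
##
## Internally everything is slope--intercept: P(theta) =
## chi + (gamma - chi) * logistic(a' theta + d). MDIFF/MDISC are derived
## views of (a, d).

## Flat matrix view of a bank for the vectorised hot paths (CAT loops,
## calibration). Computed once per session/fit, then only plain numerics.
bankMatrices <- function(bank) {
  A <- loadingMatrix(bank)
  list(
    A = A,
    d = vapply(bank@items, function(it) it@intercept, numeric(1)),
    lo = vapply(bank@items, function(it) it@lowerAsymptote, numeric(1)),
    up = vapply(bank@items, function(it) it@upperAsymptote, numeric(1)),
    ids = rownames(A),
    primary = vapply(bank@items, function(it) it@primaryDimension,
                     integer(1)),
    D = nDimensions(bank)
  )
}

## Vectorised response probabilities for all items of a flat bank at one
## theta. Returns list(p = 4PL probability, pstar = inner logistic).
bankProb <- function(bm, theta) {
  u <- drop(bm$A %*% theta) + bm$d
  pstar <- plogis(u)
  list(p = bm$lo + (bm$up - bm$lo) * pstar, pstar = pstar)
}

## Per-item Fisher information coefficients c_j(theta); the item information
## matrix is c_j * a_j a_j'. Degenerate P in {0, 1} yields 0 (information
## vanishes at the asymptotes).
bankInfoCoef <- function(bm, theta) {
  pr <- bankProb(bm, theta)
  num <- ((bm$up - bm$lo) * pr$pstar * (1 - pr$pstar))^2
  den <- pr$p * (1 - pr$p)
  cc <- ifelse(den < .EPS, 0, num / den)
  cc
}

checkTheta <- function(item, theta) {
  if (length(theta) != length(item@loadings))
    stop("theta has length ", length(theta), " but item \"", item@itemId,
         "\" has ", length(item@loadings), " loadings")
  if (any(!is.finite(theta)))
    stop("theta must be finite")
  invisible(TRUE)
}

#' 4PL probability of a correct response
#'
#' Evaluates \eqn{P(\theta) = \chi + (\gamma - \chi)\,
#' \mathrm{logistic}(a^\top\theta + d)}. The value always lies strictly
#' between the item's asymptotes and equals \eqn{(\chi + \gamma)/2} where the
#' inner logistic argument is zero.
#'
#' @param item an \linkS4class{ItemParameters}.
#' @param theta numeric trait vector matching the item's dimensionality.
#' @return Probability of a correct response.
#' @examples
#' it <- itemParameters("x", c(1.5, 0), -1, 0.2, 0.95)
#' probCorrect(it, c(1, 0))  # 0.2 + 0.75 * plogis(0.5)
#' @export
probCorrect <- function(item, theta) {
  checkTheta(item, theta)
  chi <- item@lowerAsymptote
  gma <- item@upperAsymptote
  unname(chi + (gma - chi) * plogis(sum(item@loadings * theta) +
                                      item@intercept))
}

#' Fisher information matrix of one item
#'
#' For a Bernoulli response under the 4PL model the expected information at
#' \eqn{\theta} is the rank-one matrix
#' \deqn{I_j(\theta) = \frac{[(\gamma-\chi)\,p^*(1-p^*)]^2}{P(1-P)}\,
#'   a a^\top,}
#' with \eqn{p^*} the inner logistic and \eqn{P} the 4PL probability. Where
#' \eqn{P} degenerates to 0 or 1 the zero matrix is returned.
#'
#' @inheritParams probCorrect
#' @return D x D symmetric positive-semidefinite matrix of rank at most one.
#' @export
itemInformation <- function(item, theta) {
  checkTheta(item, theta)
  a <- item@loadings
  pstar <- plogis(sum(a * theta) + item@intercept)
  span <- item@upperAsymptote - item@lowerAsymptote
  p <- item@lowerAsymptote + span * pstar
  den <- p * (1 - p)
  if (den < .EPS) return(matrix(0, length(a), length(a)))
  coef <- (span * pstar * (1 - pstar))^2 / den
  coef * tcrossprod(a)
}

#' Accumulated test information
#'
#' Sum of the Fisher information of the administered items at `theta`, plus
#' the prior precision. With nothing administered this is exactly the prior
#' precision, and adding an item can never decrease any eigenvalue.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param administered character vector of administered item ids.
#' @param theta numeric trait vector.
#' @param priorPrecision D x D matrix; defaults to the inverse of the bank's
#'   trait covariance.
#' @return D x D symmetric positive-definite information matrix.
#' @export
testInformation <- function(bank, administered, theta,
                            priorPrecision = solve(traitCov(bank))) {
  ids <- itemIds(bank)
  unknown <- setdiff(administered, ids)
  if (length(unknown))
    stop("unknown item id(s): ", paste(unknown, collapse = ", "))
  M <- priorPrecision
  if (length(administered)) {
    bm <- bankMatrices(bank)
    idx <- match(administered, ids)
    cc <- bankInfoCoef(bm, theta)[idx]
    Asub <- bm$A[idx, , drop = FALSE]
    M <- M + crossprod(Asub, cc * Asub)
  }
  unname(M)
}

#' Reckase multidimensional discrimination and difficulty
#'
#' `mdisc` is the Euclidean norm of the loading vector; `mdiff` is
#' \eqn{-d / \mathrm{MDISC}}, the signed distance from the origin to the
#' steepest point of the item response surface. `mdiff(..., flipSign=TRUE)`
#' multiplies by −1, the display convention under which difficulty increases
#' from left to right.
#'
#' @inheritParams probCorrect
#' @param flipSign logical; return the sign-flipped display value.
#' @return A nonnegative scalar (`mdisc`) or a real scalar (`mdiff`).
#' @examples
#' it <- itemParameters("x", c(3, 4), 5)
#' mdisc(it)  # 5
#' mdiff(it)  # -1
#' @export
mdisc <- function(item) {
  sqrt(sum(item@loadings^2))
}

#' @rdname mdisc
#' @export
mdiff <- function(item, flipSign = FALSE) {
  md <- mdisc(item)
  if (md < .EPS)
    stop("MDIFF is undefined for item \"", item@itemId,
         "\": zero discrimination")
  val <- -item@intercept / md
  if (flipSign) -val else val
}

## Vectorised MDIFF/MDISC over a whole bank (used by generators/summaries).
bankMdiff <- function(bank) {
  bm <- bankMatrices(bank)
  md <- sqrt(rowSums(bm$A^2))
  if (any(md < .EPS)) stop("MDIFF undefined: zero-discrimination item")
  setNames(-bm$d / md, bm$ids)
}

bankMdisc <- function(bank) {
  bm <- bankMatrices(bank)
  setNames(sqrt(rowSums(bm$A^2)), bm$ids)
}
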