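## Fixtures are built in code; the heavy reference simulations are cached so
## several test files can share one computation.

## Small unidimensional 2PL bank with a spread of difficulties.
bank1d <- function(J = 30, aRange = c(1, 2.5), seed = 11) {
  set.seed(seed)
  a <- runif(J, aRange[1], aRange[2])
  md <- seq(-2, 2, length.out = J)
  items <- lapply(seq_len(J), function(j) {
    itemParameters(sprintf("u%02d", j), a[j], -md[j] * a[j],
                   scaleLabel = "trait",
                   startAgeGroup = if (j == 3L) "5" else "")
  })
  itemBank(items, "trait")
}

## Small two-dimensional bank, one loading per item, correlated traits.
bank2d <- function(J = 16, rho = 0.5, seed = 12) {
  set.seed(seed)
  items <- lapply(seq_len(J), function(j) {
    dim <- 1L + (j %% 2L)
    a <- rep(0, 2)
    a[dim] <- runif(1, 1, 2.5)
    itemParameters(sprintf("b%02d", j), a, rnorm(1, 0, 1.2),
                   lowerAsymptote = runif(1, 0, 0.2),
                   upperAsymptote = runif(1, 0.9, 1),
                   primaryDimension = dim,
                   scaleLabel = paste0("s", dim),
                   startAgeGroup = if (j == 1L) "5" else "")
  })
  itemBank(items, c("s1", "s2"),
           traitCov = matrix(c(1, rho, rho, 1), 2))
}

## Brute-force grid maximisation of the exact log posterior (independent of
## the package's optimiser; probabilities recomputed from the item slots).
gridMapOracle <- function(bank, administered, responses, step = 0.01,
                          lim = 4) {
  D <- nDimensions(bank)
  stopifnot(D <= 2)
  priorPrec <- solve(traitCov(bank))
  its <- lapply(administered, function(id) getItem(bank, id))
  g <- seq(-lim, lim, by = step)
  pts <- if (D == 1L) matrix(g, ncol = 1) else
    as.matrix(expand.grid(g, g))
  lp <- -0.5 * rowSums((pts %*% priorPrec) * pts)
  for (i in seq_along(its)) {
    it <- its[[i]]
    p <- it@lowerAsymptote + (it@upperAsymptote - it@lowerAsymptote) *
      plogis(drop(pts %*% it@loadings) + it@intercept)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    lp <- lp + if (responses[i] == 1) log(p) else log(1 - p)
  }
  pts[which.max(lp), ]
}

## Finite-difference Fisher information of one item: the expectation over
## the Bernoulli response of the squared score, with gradients taken by
## central differences of the log-probabilities.
fdItemInformation <- function(item, theta, h = 1e-5) {
  D <- length(item@loadings)
  pAt <- function(th) {
    item@lowerAsymptote + (item@upperAsymptote - item@lowerAsymptote) *
      plogis(sum(item@loadings * th) + item@intercept)
  }
  gLogP <- numeric(D)
  gLog1mP <- numeric(D)
  for (k in seq_len(D)) {
    e <- rep(0, D); e[k] <- h
    gLogP[k] <- (log(pAt(theta + e)) - log(pAt(theta - e))) / (2 * h)
    gLog1mP[k] <- (log(1 - pAt(theta + e)) -
                     log(1 - pAt(theta - e))) / (2 * h)
  }
  p <- pAt(theta)
  p * tcrossprod(gLogP) + (1 - p) * tcrossprod(gLog1mP)
}

## Shared heavy computations: the reference synthetic bank + simulees and
## the AP-rule simulation runs at the three SEM thresholds.
.refCache <- new.env(parent = emptyenv())

referenceFixture <- function() {
  if (!exists("fx", envir = .refCache))
    assign("fx", makeReferenceFixture(seed = 1, nSimulees = 200L),
           envir = .refCache)
  get("fx", envir = .refCache)
}

referenceRun <- function(rel, n = 200L) {
  key <- sprintf("run_%s_%d", rel, n)
  if (!exists(key, envir = .refCache)) {
    fx <- referenceFixture()
    assign(key, runCatSimulation(
      fx$bank, fx$simulees[seq_len(n), , drop = FALSE], rule = "AP",
      stopConfig = semThresholdStop(semFromReliability(rel)), seed = 100
    ), envir = .refCache)
  }
  get(key, envir = .refCache)
}
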