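simulate2pl <- function(N, J, seed = 42) {
  set.seed(seed)
  a <- exp(rnorm(J, log(1.5), 0.3))
  d <- rnorm(J, 0, 1)
  th <- rnorm(N)
  P <- plogis(outer(th, a) + matrix(d, N, J, byrow = TRUE))
  X <- matrix(rbinom(N * J, 1, P), N, J)
  colnames(X) <- sprintf("it%02d", seq_len(J))
  list(X = X, a = a, d = d)
}

test_that("free-parameter counts follow the nested family structure", {
  lp1 <- matrix(1, 10, 1)
  expect_identical(countParameters(modelSpec("M2PL", lp1)), 20L)

  lp <- matrix(0, 12, 3)
  lp[cbind(1:12, rep(1:3, each = 4))] <- 1
  lp[1:4, 3] <- 1  # bifactor cross-loadings
  for (corr in c(FALSE, TRUE)) {
    q2 <- countParameters(modelSpec("M2PL", lp, correlatedTraits = corr))
    q3 <- countParameters(modelSpec("M3PL", lp, correlatedTraits = corr))
    q4 <- countParameters(modelSpec("M4PL", lp, correlatedTraits = corr))
    expect_identical(q3 - q2, 12L)  # one lower asymptote per item
    expect_identical(q4 - q3, 12L)  # one upper asymptote per item
  }
  # correlated content traits add the free correlations
  expect_identical(
    countParameters(modelSpec("M2PL", lp, correlatedTraits = TRUE)) -
      countParameters(modelSpec("M2PL", lp)),
    3L
  )
})

test_that("calibration recovers 2PL parameters at moderate scale", {
  sim <- simulate2pl(500, 12, seed = 101)
  fit <- fitMirt(sim$X, modelSpec("M2PL", matrix(1, 12, 1)),
                 nStarts = 2, seed = 5)
  aH <- loadingMatrix(fit@bank)[, 1]
  dH <- vapply(bankItems(fit@bank), function(i) i@intercept, numeric(1))
  # at this deliberately small N the slope range is narrow, so the slope
  # correlation is noise-limited; intercepts are tightly determined
  expect_gt(cor(aH, sim$a), 0.5)
  expect_lt(sqrt(mean((aH - sim$a)^2)), 0.4)
  expect_gt(cor(dH, sim$d), 0.95)
  expect_lt(abs(mean(dH - sim$d)), 0.1)
  expect_true(fit@converged)
})

test_that("multi-start estimation is deterministic in the seed", {
  sim <- simulate2pl(200, 8, seed = 7)
  f1 <- fitMirt(sim$X, modelSpec("M2PL", matrix(1, 8, 1)),
                nStarts = 3, seed = 99)
  f2 <- fitMirt(sim$X, modelSpec("M2PL", matrix(1, 8, 1)),
                nStarts = 3, seed = 99)
  expect_identical(f1@logLik, f2@logLik)
  expect_identical(loadingMatrix(f1@bank), loadingMatrix(f2@bank))
  expect_identical(f1@startLogLiks, f2@startLogLiks)
})

test_that("degenerate items are flagged for removal, not estimated", {
  sim <- simulate2pl(200, 8, seed = 8)
  X <- cbind(sim$X, allcorrect = 1L)
  fit <- fitMirt(X, modelSpec("M2PL", matrix(1, 9, 1)),
                 nStarts = 1, seed = 3)
  expect_identical(fit@removedItems, "allcorrect")
  expect_identical(length(bankItems(fit@bank)), 8L)
})

test_that("missing responses drop out of the likelihood", {
  sim <- simulate2pl(300, 10, seed = 9)
  X <- sim$X
  set.seed(1)
  X[sample(length(X), length(X) %/% 5)] <- NA
  fit <- fitMirt(X, modelSpec("M2PL", matrix(1, 10, 1)),
                 nStarts = 1, seed = 3)
  expect_true(is.finite(fit@logLik))
  aH <- loadingMatrix(fit@bank)[, 1]
  expect_gt(cor(aH, sim$a), 0.4)
  dH <- vapply(bankItems(fit@bank), function(i) i@intercept, numeric(1))
  expect_gt(cor(dH, sim$d), 0.9)
})

test_that("nested families never lose marginal likelihood", {
  sim <- simulate2pl(400, 8, seed = 12)
  lp <- matrix(1, 8, 1)
  f2 <- fitMirt(sim$X, modelSpec("M2PL", lp), nStarts = 2, seed = 4)
  f3 <- fitMirt(sim$X, modelSpec("M3PL", lp), nStarts = 2, seed = 4)
  expect_gte(f3@logLik, f2@logLik - 0.5)
})

test_that("two-dimensional confirmatory calibration recovers correlated traits", {
  set.seed(31)
  N <- 600; J <- 12; rho <- 0.6
  Sigma <- matrix(c(1, rho, rho, 1), 2)
  th <- MASS::mvrnorm(N, c(0, 0), Sigma)
  lp <- matrix(0, J, 2)
  lp[cbind(1:J, rep(1:2, each = J / 2))] <- 1
  a <- exp(rnorm(J, log(1.5), 0.2))
  A <- lp * a
  d <- rnorm(J)
  P <- plogis(th %*% t(A) + matrix(d, N, J, byrow = TRUE))
  X <- matrix(rbinom(N * J, 1, P), N, J)
  colnames(X) <- sprintf("c%02d", 1:J)
  fit <- fitMirt(X, modelSpec("M2PL", lp, correlatedTraits = TRUE),
                 nStarts = 1, seed = 6)
  expect_equal(traitCov(fit@bank)[1, 2], rho, tolerance = 0.15)
  expect_gt(cor(loadingMatrix(fit@bank)[lp == 1], a), 0.8)
})
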