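makeIndices <- function(label, srmsr, n = 307L) {
  new("FitIndices", m2 = 100, df = 50, p = 0.5, rmsea = 0.02,
      rmseaCI = c(0.01, 0.03), srmsr = srmsr, tli = 0.99, cfi = 0.99,
      logLik = -1000, nObs = n, nParameters = 10L, label = label)
}

test_that("M2 degrees of freedom follow the margin arithmetic", {
  # J univariate + J(J-1)/2 bivariate margins minus free parameters
  expect_identical(m2DegreesOfFreedom(177, 408), 15345L)
  expect_identical(m2DegreesOfFreedom(177, 585), 15168L)
  expect_identical(m2DegreesOfFreedom(177, 762), 14991L)
  expect_identical(m2DegreesOfFreedom(10, 20), 10L + 45L - 20L)
})

test_that("fit indices behave under a correctly specified model", {
  set.seed(42)
  J <- 10; N <- 800
  a <- exp(rnorm(J, log(1.5), 0.3)); d <- rnorm(J)
  th <- rnorm(N)
  X <- matrix(rbinom(N * J, 1,
                     plogis(outer(th, a) + matrix(d, N, J, byrow = TRUE))),
              N, J)
  colnames(X) <- sprintf("f%02d", 1:J)
  fit <- fitMirt(X, modelSpec("M2PL", matrix(1, J, 1)),
                 nStarts = 1, seed = 2)
  fi <- fitIndices(fit, X)
  expect_identical(fi@df, as.numeric(m2DegreesOfFreedom(J, 2L * J)))
  expect_lt(fi@rmsea, 0.05)
  expect_gt(fi@cfi, 0.95)
  expect_gt(fi@tli, 0.9)
  expect_lt(fi@srmsr, 0.05)
  expect_true(fi@rmseaCI[1] <= fi@rmsea + 1e-9 &&
                fi@rmsea <= fi@rmseaCI[2] + 1e-9)

  Xna <- X; Xna[1, 1] <- NA
  expect_error(fitIndices(fit, Xna), "complete")
})

test_that("model comparison ranks by SRMSR with stable ties", {
  a <- makeIndices("M4PL-10", 0.0563)
  b <- makeIndices("M2PL-1", 0.0641)
  tab <- compareModels(list(b, a))
  expect_identical(tab$label, c("M4PL-10", "M2PL-1"))

  # identical indices: input order preserved
  t1 <- makeIndices("first", 0.05)
  t2 <- makeIndices("second", 0.05)
  expect_identical(compareModels(list(t1, t2))$label, c("first", "second"))

  # single fit: single-row table
  expect_identical(nrow(compareModels(list(a))), 1L)

  # mixed response sets are refused
  expect_error(compareModels(list(a, makeIndices("other", 0.03, n = 100L))),
               "different response sets")
})
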