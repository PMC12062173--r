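test_that("the default synthetic bank matches the target geometry", {
  b <- generateBank(bankSpec(), seed = 1)
  expect_identical(length(bankItems(b)), 177L)
  expect_identical(nDimensions(b), 8L)           # 6 content + 2 nuisance
  expect_identical(length(reportedDimensions(b)), 6L)

  md <- vapply(bankItems(b), mdiff, numeric(1))
  ms <- vapply(bankItems(b), mdisc, numeric(1))
  expect_true(all(md >= -2 - 1e-9 & md <= 2 + 1e-9))
  # the generated pool spans the full band
  expect_lt(min(md), -2 + 0.2)
  expect_gt(max(md), 2 - 0.2)
  # majority of items highly discriminating
  expect_gt(mean(ms > 1.5), 0.5)
  expect_true(all(ms > 0))

  # asymptote ordering per item
  for (it in bankItems(b))
    expect_lt(it@lowerAsymptote, it@upperAsymptote)

  # per-scale counts honour the spec
  sc <- table(vapply(bankItems(b), function(it) it@scaleLabel, character(1)))
  expect_identical(sort(as.integer(sc)), sort(unname(bankSpec()@nItemsPerScale)))

  # three age-group starting items, increasingly difficult
  st <- startingItems(b)
  expect_identical(sort(names(st)), c("4", "5", "6"))
  mdStart <- vapply(st, function(id) mdiff(getItem(b, id)), numeric(1))
  expect_true(all(diff(mdStart[c("4", "5", "6")]) > 0))
})

test_that("bifactor block items load on a nuisance dimension", {
  b <- generateBank(bankSpec(), seed = 2)
  A <- loadingMatrix(b)
  nuisCols <- which(b@nuisanceDimensions)
  nLoaded <- sum(rowSums(abs(A[, nuisCols, drop = FALSE])) > 0)
  expect_identical(nLoaded, 20L)  # default block size
  # bifactor items keep their MDISC equal to the loading norm
  expect_true(all(abs(sqrt(rowSums(A^2)) -
                        vapply(bankItems(b), mdisc, numeric(1))) < 1e-9))
})

test_that("generation is seed-deterministic and round-trips through files", {
  b1 <- generateBank(bankSpec(), seed = 42)
  b2 <- generateBank(bankSpec(), seed = 42)
  expect_identical(loadingMatrix(b1), loadingMatrix(b2))
  expect_identical(startingItems(b1), startingItems(b2))

  csv <- tempfile(fileext = ".csv")
  writeBank(b1, csv)
  back <- readBank(csv, dimensionLabels = dimensionLabels(b1),
                   traitCov = traitCov(b1),
                   nuisanceDimensions = b1@nuisanceDimensions)
  expect_equal(loadingMatrix(back), loadingMatrix(b1))
  expect_identical(itemIds(back), itemIds(b1))
  expect_identical(startingItems(back), startingItems(b1))

  js <- tempfile(fileext = ".json")
  writeBank(b1, js)
  backJs <- readBank(js)
  expect_equal(loadingMatrix(backJs), loadingMatrix(b1))
  expect_equal(traitCov(backJs), traitCov(b1))
  expect_identical(backJs@nuisanceDimensions, b1@nuisanceDimensions)
})

test_that("the reference fixture is stable and self-consistent", {
  fx1 <- makeReferenceFixture(seed = 1, nSimulees = 50L)
  fx2 <- makeReferenceFixture(seed = 1, nSimulees = 50L)
  expect_identical(fx1$digest, fx2$digest)
  expect_identical(length(bankItems(fx1$bank)), 177L)
  expect_identical(dim(fx1$simulees), c(50L, 8L))
  # simulee covariance tracks the bank prior at larger n
  fxBig <- makeReferenceFixture(seed = 1, nSimulees = 5000L)
  expect_lt(max(abs(cov(fxBig$simulees) - traitCov(fxBig$bank))), 0.1)
})

test_that("infeasible specs are refused", {
  expect_error(bankSpec(nItemsPerScale = c(a = 5L, b = 0L)), "at least one")
  expect_error(bankSpec(traitCorrelation = 1), "traitCorrelation")
})
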