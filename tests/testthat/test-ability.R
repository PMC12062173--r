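test_that("MAP estimate matches analytic and symmetric cases", {
  b <- itemBank(list(
    itemParameters("i1", 1, 0), itemParameters("i2", 1, 0, scaleLabel = "t")
  ), "t")

  # prior-only posterior: the prior mean with unit SEM
  e0 <- mapEstimate(b, character(0), integer(0))
  expect_equal(unname(theta(e0)), 0)
  expect_equal(unname(sem(e0)), 1)

  # one correct response on a unit-slope item: mode solves theta = 1 - P
  e1 <- mapEstimate(b, "i1", 1)
  expect_equal(unname(theta(e1)), 0.400, tolerance = 0.005)

  # one correct + one incorrect on identical items: symmetry
  e2 <- mapEstimate(b, c("i1", "i2"), c(1L, 0L))
  expect_equal(unname(theta(e2)), 0, tolerance = 1e-6)

  expect_error(mapEstimate(b, "i1", c(1, 0)), "same length")
  expect_error(mapEstimate(b, "i1", 2), "0/1")
})

test_that("MAP agrees with brute-force grid maximisation of the posterior", {
  set.seed(23)
  b1 <- bank1d(20)
  b2 <- bank2d(16)
  for (rep in 1:70) {
    k <- sample(2:8, 1)
    ids <- sample(itemIds(b1), k)
    resp <- rbinom(k, 1, 0.5)
    est <- mapEstimate(b1, ids, resp)
    oracle <- gridMapOracle(b1, ids, resp)
    expect_lt(max(abs(unname(theta(est)) - unname(oracle))), 0.02)
  }
  for (rep in 1:30) {
    k <- sample(3:8, 1)
    ids <- sample(itemIds(b2), k)
    resp <- rbinom(k, 1, 0.5)
    est <- mapEstimate(b2, ids, resp)
    oracle <- gridMapOracle(b2, ids, resp)
    expect_lt(max(abs(unname(theta(est)) - unname(oracle))), 0.02)
  }
})

test_that("SEM shrinks as informative items accumulate", {
  # at a fixed evaluation point, information is additive, so the implied
  # SEM is strictly nonincreasing item by item
  b <- bank1d(20)
  ids <- itemIds(b)[order(abs(vapply(bankItems(b), mdiff, numeric(1))))]
  semAt <- vapply(1:10, function(k) {
    sqrt(solve(testInformation(b, ids[1:k], 0))[1, 1])
  }, numeric(1))
  expect_true(all(diff(semAt) <= 1e-12))

  # along a real scoring trajectory the MAP moves between items, so allow
  # small transient increases but require overall shrinkage
  set.seed(9)
  resp <- rbinom(10, 1, 0.5)
  sems <- vapply(1:10, function(k) {
    unname(sem(mapEstimate(b, ids[1:k], resp[1:k],
                           information = "expected")))
  }, numeric(1))
  expect_true(all(diff(sems) <= 0.05))
  expect_lt(sems[10], sems[1])
})

test_that("SEM-reliability conversion round-trips exactly", {
  r <- seq(0, 0.99, by = 0.01)
  expect_equal(reliabilityFromSem(semFromReliability(r)), r,
               tolerance = 1e-14)
  expect_equal(semFromReliability(0.8), sqrt(0.2))
  expect_error(semFromReliability(1.0), "\\[0, 1\\)")
  expect_error(reliabilityFromSem(-0.1), "nonnegative")
})

test_that("T-scores are the standard linear transform", {
  expect_equal(tScore(c(0, 1, -2)), c(50, 60, 30))
  b <- bank1d(10)
  e <- mapEstimate(b, itemIds(b)[1], 1L)
  expect_equal(unname(tScores(e)), 50 + 10 * unname(theta(e)))
  expect_equal(unname(reliability(e)), 1 - unname(sem(e))^2)
})
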