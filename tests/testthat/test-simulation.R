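test_that("simulated responses are Bernoulli draws from the 4PL model", {
  # certainty item: inner argument +20 forces a correct response
  b <- itemBank(list(itemParameters("sure", 1, 20),
                     itemParameters("coin", 0.0001, 0)), "t")
  r <- simulateResponses(b, 0, seed = 1)
  expect_identical(unname(r["sure"]), 1L)

  # determinism in the seed
  bk <- bank1d(25)
  expect_identical(simulateResponses(bk, 0.5, seed = 7),
                   simulateResponses(bk, 0.5, seed = 7))
  expect_false(identical(simulateResponses(bk, 0.5, seed = 7),
                         simulateResponses(bk, 0.5, seed = 8)))

  # empirical rate over many identical items within 3 binomial SDs
  n <- 4000
  p <- probCorrect(itemParameters("x", 1.2, -0.4, 0.15, 0.95), 0.3)
  big <- itemBank(lapply(seq_len(n), function(i)
    itemParameters(paste0("r", i), 1.2, -0.4, 0.15, 0.95)), "t")
  rate <- mean(simulateResponses(big, 0.3, seed = 5))
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("simulee populations honour the prior and the seed", {
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_identical(nrow(generateSimulees(0, c(0, 0), S)), 0L)
  m1 <- generateSimulees(100, c(0, 0), S, seed = 3)
  expect_identical(m1, generateSimulees(100, c(0, 0), S, seed = 3))
  big <- generateSimulees(50000, c(0, 0), S, seed = 4)
  expect_lt(max(abs(cov(big) - S)), 0.05)
  expect_error(generateSimulees(5, c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("nearest-rank percentiles use the documented convention", {
  nr <- mcat4pl:::nearestRankPercentile
  expect_identical(nr(rep(7, 9), 50), 7)           # constant vector median
  expect_identical(nr(1:10, 75), 8L)               # ceil(0.75 * 10) = 8
  expect_identical(nr(1:10, c(5, 95)), c(1L, 10L))
})

test_that("a degenerate one-item bank exhausts immediately", {
  b <- itemBank(list(itemParameters("solo", 1.5, 0,
                                    startAgeGroup = "5")), "t")
  s <- runCatSimulation(b, matrix(rnorm(5), 5, 1), rule = "D",
                        stopConfig = semThresholdStop(0.3), seed = 1)
  expect_true(all(s@itemCounts == 1L))
  expect_true(all(s@stopReasons == "bank_exhausted"))
})

test_that("summaries are deterministic and track the stopping rule", {
  b <- bank2d(40, seed = 31)
  sim <- generateSimulees(12, c(0, 0), traitCov(b), seed = 5)
  s1 <- runCatSimulation(b, sim, rule = "D",
                         stopConfig = semThresholdStop(0.55), seed = 20)
  s2 <- runCatSimulation(b, sim, rule = "D",
                         stopConfig = semThresholdStop(0.55), seed = 20)
  expect_identical(s1@itemCounts, s2@itemCounts)
  expect_identical(s1@itemCountStats, s2@itemCountStats)

  # the stricter rule never needs fewer items, simulee by simulee
  s3 <- runCatSimulation(b, sim, rule = "D",
                         stopConfig = semThresholdStop(0.45), seed = 20)
  expect_true(all(s3@itemCounts >= s1@itemCounts))
  expect_true(all(s1@terminalReliability > 0 & s1@terminalReliability < 1))
})

test_that("the starting-item regression recovers planted effects", {
  set.seed(77)
  groups <- c("4", "5", "6")
  items <- list("4" = c("ref4", "good4", "mid4"),
                "5" = c("ref5", "alt5"),
                "6" = c("ref6", "alt6"))
  delta <- 5
  rows <- list()
  for (g in groups) for (it in items[[g]]) for (rule in c("strict", "loose"))
    for (rep in 1:30) {
      y <- 50 + (rule == "loose") * 3 - (it == "good4") * delta +
        rnorm(1, 0, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        age_group = g, start_item = it, stop_rule = rule, sss = y)
    }
  res <- do.call(rbind, rows)
  tab <- startingItemRegression(
    res, referenceLevels = c("4" = "ref4", "5" = "ref5", "6" = "ref6"),
    looserRule = "loose")

  good <- tab[tab$term == "good4", ]
  expect_lt(abs(good$b - (-delta)), 2 * good$SE)
  # the looser rule raises the outcome by construction: positive coefficient
  expect_gt(tab$b[tab$term == "stop_rule"], 0)
  # within an age group the most beneficial item is listed first
  g4 <- tab[tab$age_group == "4", ]
  expect_identical(g4$term[1], "good4")
  expect_true(all(diff(g4$b) >= 0))

  # intercept with all dummies at reference equals the reference cell mean
  noiseFree <- res
  noiseFree$sss <- 50 + (noiseFree$stop_rule == "loose") * 3 -
    (noiseFree$start_item == "good4") * delta
  tab0 <- suppressWarnings(startingItemRegression(  # zero-residual fit
    noiseFree, referenceLevels = c("4" = "ref4", "5" = "ref5", "6" = "ref6"),
    looserRule = "loose"))
  expect_equal(tab0$b[tab0$term == "(Intercept)"], 50, tolerance = 1e-8)

  expect_error(startingItemRegression(res[, 1:3]), "columns")
  one <- res[res$age_group != "4" | res$start_item == "ref4", ]
  expect_error(startingItemRegression(
    one, referenceLevels = c("4" = "ref4", "5" = "ref5", "6" = "ref6")),
    "2 start-item levels")
})

test_that("session-driven starting-item study produces usable outcomes", {
  b <- bank2d(40, seed = 31)
  sim <- generateSimulees(4, c(0, 0), traitCov(b), seed = 9)
  cand <- list("5" = itemIds(b)[1:2])
  out <- startingItemStudy(
    b, sim, rep("5", 4), cand,
    stopConfigs = list(s45 = semThresholdStop(0.45)),
    rule = "D", seed = 3)
  expect_identical(nrow(out), 8L)
  expect_true(all(is.finite(out$sss)))
  expect_true(all(out$start_item %in% cand[["5"]]))
})
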