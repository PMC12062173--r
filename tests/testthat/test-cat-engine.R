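test_that("starting items resolve by age bucket", {
  b <- bank2d()
  expect_identical(selectStartingItem(b, "5"), "b01")
  b3 <- itemBank(list(
    itemParameters("e1", 1, 1.5, startAgeGroup = "4", scaleLabel = "t"),
    itemParameters("e2", 1, 1.0, startAgeGroup = "5", scaleLabel = "t"),
    itemParameters("e3", 1, 0.5, startAgeGroup = "6", scaleLabel = "t"),
    itemParameters("e4", 1, 0)
  ), "t")
  expect_identical(selectStartingItem(b3, "4;6"), "e1")
  expect_identical(selectStartingItem(b3, 5), "e2")
  expect_identical(selectStartingItem(b3, "7;2"), "e3")
  noStart <- itemBank(list(itemParameters("x", 1, 0)), "t")
  expect_error(selectStartingItem(noStart, "5"), "no starting items")
  expect_error(selectStartingItem(b3, "toddler"), "unmapped age group")
})

test_that("selection rules reduce to maximum information in one dimension", {
  # two 2PL candidates a=2 vs a=1 at the current estimate: information
  # 4 P(1-P) vs P(1-P), so every determinant/trace/eigen/A criterion picks
  # the steeper item
  b <- itemBank(list(
    itemParameters("s", 1, 0, startAgeGroup = "5"),
    itemParameters("lo", 1, 0),
    itemParameters("hi", 2, 0)
  ), "t")
  ses <- catSession(b, "5")
  ses <- administer(ses, "s", 1L)
  for (rule in c("D", "T", "A", "E", "TP", "AP", "EP"))
    expect_identical(nextItem(ses, rule), "hi")

  # D-rule in 1-D is max-information selection at every step
  b1 <- bank1d(15)
  set.seed(4)
  ses <- catSession(b1, "5", rule = "D",
                    stopConfig = semThresholdStop(0.05))
  ses <- administer(ses, nextItem(ses), 1L)
  for (step in 1:6) {
    pick <- nextItem(ses, "D")
    cand <- setdiff(itemIds(b1), administeredItems(ses))
    th <- unname(theta(currentEstimate(ses)))
    info <- vapply(cand, function(id)
      itemInformation(getItem(b1, id), th)[1, 1], numeric(1))
    expect_identical(pick, cand[which.max(info)])
    expect_identical(nextItem(ses, "T"), pick)
    expect_identical(nextItem(ses, "E"), pick)
    ses <- administer(ses, pick, rbinom(1, 1, 0.5))
  }
})

test_that("a single remaining candidate is selected under every rule", {
  b <- itemBank(list(
    itemParameters("s", 1, 0, startAgeGroup = "5"),
    itemParameters("only", 1.5, 0.3)
  ), "t")
  ses <- administer(catSession(b, "5"), "s", 1L)
  for (rule in c("D", "T", "A", "W", "E", "TP", "AP", "WP", "EP"))
    expect_identical(nextItem(ses, rule), "only")
})

test_that("the staged stopping rule follows the published thresholds", {
  cfg <- stopRuleConfig()
  rd <- 1:6
  mk <- function(k, lastRow) {
    m <- matrix(0.9, k, 6)
    m[k, ] <- lastRow
    m
  }
  sc <- mcat4pl:::stopCheckInternal
  # 30 items, all six SEMs 0.30 < 0.3873: stage-1 stop
  expect_identical(sc(mk(30, rep(0.30, 6)), 30L, cfg, rd, FALSE),
                   list(stop = TRUE, reason = "stage1_sem"))
  # one dimension at 0.40 blocks stage 1, and stage 2 is not yet active
  expect_false(sc(mk(30, c(0.40, rep(0.30, 5))), 30L, cfg, rd, FALSE)$stop)
  # from item 50 the looser 0.4472 threshold applies
  expect_identical(sc(mk(55, rep(0.42, 6)), 55L, cfg, rd, FALSE),
                   list(stop = TRUE, reason = "stage2_sem"))
  # 0.42 would have failed stage 1
  expect_false(sc(mk(49, rep(0.42, 6)), 49L, cfg, rd, FALSE)$stop)

  # stability: all six ranges 0.008 give 6 * 0.008^2 = 0.000384 < 0.0005
  m <- matrix(0.6, 65, 6)
  m[56:65, ] <- 0.6 + outer(seq(0, 0.008, length.out = 10), rep(1, 6))
  expect_identical(sc(m, 65L, cfg, rd, FALSE),
                   list(stop = TRUE, reason = "stability"))
  # ranges of 0.02 keep the session running
  m2 <- matrix(0.6, 65, 6)
  m2[56:65, ] <- 0.6 + outer(seq(0, 0.02, length.out = 10), rep(1, 6))
  expect_false(sc(m2, 65L, cfg, rd, FALSE)$stop)
  # exhaustion always stops
  expect_identical(sc(m2, 65L, cfg, rd, TRUE),
                   list(stop = TRUE, reason = "bank_exhausted"))
})

test_that("administer appends, rescoring moves with the response", {
  b <- bank1d(20)
  ses <- catSession(b, "5")
  ses <- administer(ses, nextItem(ses), 1L)
  expect_identical(length(administeredItems(ses)), 1L)
  th1 <- estimateHistory(ses)$theta[1, 1]
  pick <- nextItem(ses)
  sesUp <- administer(ses, pick, 1L)
  sesDn <- administer(ses, pick, 0L)
  # a correct response on an on-dimension item never lowers the MAP
  expect_gte(estimateHistory(sesUp)$theta[2, 1], th1 - 1e-8)
  expect_lte(estimateHistory(sesDn)$theta[2, 1], th1 + 1e-8)

  expect_error(administer(sesUp, pick, 1L), "already administered")
  expect_error(administer(ses, "nope", 1L), "unknown item")
})

test_that("sessions terminate on finite banks and refuse further items", {
  b <- bank1d(6)
  ses <- runSession(b, "5", rule = "D",
                    stopConfig = semThresholdStop(0.05),
                    trueTheta = 0.3, seed = 2)
  expect_true(isStopped(ses))
  expect_identical(stopReason(ses), "bank_exhausted")
  expect_identical(length(administeredItems(ses)), 6L)
  expect_error(administer(ses, itemIds(b)[1], 1L), "already stopped")
})

test_that("threshold stops guarantee the reliability floor", {
  b2 <- bank2d(40, seed = 31)
  thr <- semFromReliability(0.8)
  set.seed(8)
  for (rep in 1:5) {
    ses <- runSession(b2, "5", rule = "AP",
                      stopConfig = semThresholdStop(thr),
                      trueTheta = rnorm(2) * 0.5, seed = rep)
    if (stopReason(ses) != "bank_exhausted") {
      k <- length(administeredItems(ses))
      rels <- 1 - estimateHistory(ses)$sem[k, ]^2
      expect_true(all(rels > 0.8))
    }
  }
})

test_that("difficulty adapts to responses in aggregate", {
  b <- bank1d(40, seed = 19)
  md <- setNames(vapply(bankItems(b), mdiff, numeric(1)), itemIds(b))
  afterCorrect <- c(); afterWrong <- c()
  set.seed(91)
  for (rep in 1:12) {
    ses <- runSession(b, "5", rule = "D",
                      stopConfig = semThresholdStop(0.45),
                      trueTheta = rnorm(1), seed = 500 + rep)
    ids <- administeredItems(ses)
    rsp <- sessionResponses(ses)
    if (length(ids) < 2) next
    nxt <- md[ids[-1]]
    prev <- rsp[-length(rsp)]
    afterCorrect <- c(afterCorrect, nxt[prev == 1])
    afterWrong <- c(afterWrong, nxt[prev == 0])
  }
  expect_gt(mean(afterCorrect), mean(afterWrong))
})
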