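test_that("probCorrect matches the 4PL closed form and its limits", {
  # zero slope: symmetric midpoint between the asymptotes
  flat <- itemParameters("f", c(0, 0), 0)
  expect_equal(probCorrect(flat, c(3, -7)), 0.5)
  mid <- itemParameters("m", c(0, 0), 0, 0.2, 0.9)
  expect_equal(probCorrect(mid, c(1, 1)), (0.2 + 0.9) / 2)

  # lower asymptote is the low-ability limit
  guess <- itemParameters("g", 1, 0, 0.25, 1)
  expect_equal(probCorrect(guess, -50), 0.25, tolerance = 1e-10)

  # independent evaluation of 0.2 + 0.75 * logistic(0.5)
  it <- itemParameters("x", c(1.5, 0), -1, 0.2, 0.95)
  expect_equal(probCorrect(it, c(1, 0)), 0.2 + 0.75 * plogis(0.5),
               tolerance = 1e-12)

  expect_error(probCorrect(it, 1), "loadings")
  expect_error(probCorrect(it, c(NA, 1)), "finite")
})

test_that("probCorrect is monotone and bounded over a theta grid", {
  set.seed(3)
  for (rep in 1:5) {
    it <- itemParameters("r", runif(2, 0.2, 3), rnorm(1),
                         runif(1, 0, 0.3), runif(1, 0.85, 1))
    grid <- seq(-6, 6, by = 0.25)
    for (k in 1:2) {
      th0 <- rnorm(2)
      p <- vapply(grid, function(g) {
        th <- th0; th[k] <- g; probCorrect(it, th)
      }, numeric(1))
      expect_true(all(diff(p) >= -1e-12))
      expect_true(all(p > it@lowerAsymptote & p < it@upperAsymptote))
    }
  }
})

test_that("item information matches closed forms and the FD oracle", {
  # zero slope carries no information
  expect_equal(itemInformation(itemParameters("f", c(0, 0), 1), c(1, 2)),
               matrix(0, 2, 2))
  # 2PL closed form a^2 P (1 - P) at P = 0.5
  expect_equal(itemInformation(itemParameters("a", 1, 0), 0)[1, 1], 0.25)
  # 4PL closed form (0.8 * 0.25)^2 / (0.6 * 0.4)
  expect_equal(itemInformation(itemParameters("b", 1, 0, 0.2, 1), 0)[1, 1],
               0.04 / 0.24, tolerance = 1e-12)

  set.seed(17)
  for (rep in 1:8) {
    D <- sample(1:3, 1)
    it <- itemParameters("r", runif(D, 0.3, 2.5), rnorm(1),
                         runif(1, 0, 0.3), runif(1, 0.85, 1))
    th <- rnorm(D)
    expect_equal(itemInformation(it, th), fdItemInformation(it, th),
                 tolerance = 1e-5)
  }
})

test_that("4PL reduces exactly to the 2PL when asymptotes are 0 and 1", {
  set.seed(5)
  for (rep in 1:5) {
    a <- runif(2, 0.3, 2.5); d <- rnorm(1); th <- rnorm(2)
    it <- itemParameters("r", a, d, 0, 1)
    u <- sum(a * th) + d
    expect_equal(probCorrect(it, th), plogis(u), tolerance = 1e-12)
    expect_equal(itemInformation(it, th),
                 plogis(u) * (1 - plogis(u)) * tcrossprod(a),
                 tolerance = 1e-12)
  }
})

test_that("test information accumulates from the prior precision", {
  b <- itemBank(list(
    itemParameters("o1", c(1, 0), 0),
    itemParameters("o2", c(0, 1), 0, primaryDimension = 2)
  ), c("x", "y"))
  expect_equal(testInformation(b, character(0), c(0, 0)), diag(2))
  expect_equal(testInformation(b, c("o1", "o2"), c(0, 0)),
               diag(c(1.25, 1.25)))
  # adding an item never decreases the determinant
  d1 <- det(testInformation(b, "o1", c(0, 0)))
  d2 <- det(testInformation(b, c("o1", "o2"), c(0, 0)))
  expect_gte(d2, d1)
  expect_error(testInformation(b, "nope", c(0, 0)), "unknown item")
})

test_that("MDISC and MDIFF are the Reckase summaries of the slopes", {
  it <- itemParameters("p", c(3, 4), 5)
  expect_equal(mdisc(it), 5)
  expect_equal(mdiff(it), -1)
  expect_equal(mdiff(it, flipSign = TRUE), 1)
  expect_equal(mdiff(itemParameters("q", c(1, 0), 0)), 0)
  # a hard item at the top of the -2..+2 band
  expect_equal(mdiff(itemParameters("h", 1, -2)), 2)
  expect_error(mdiff(itemParameters("z", c(0, 0), 1)), "undefined")
})
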