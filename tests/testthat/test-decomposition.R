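af4 <- function(a1 = 0.1, a2a = 0.2, a2x = 0.2, a2b = 0.5)
  c("1" = a1, "2a" = a2a, "2x" = a2x, "2b" = a2b)

test_that("predicted mass ratio follows the cylinder product", {
  expect_equal(predictedMassRatio(morphologyDelta(1, 1, af4(), 1)), 1)
  expect_equal(predictedMassRatio(morphologyDelta(1, 1, af4(), 0.5)), 0.5)
  d <- morphologyDelta(fn = 0.9,
                       csa = c("1" = 1, "2a" = 1, "2x" = 1, "2b" = 0.7),
                       af = af4(), fl = 0.8)
  expect_equal(predictedMassRatio(d), 0.612, tolerance = 1e-12)
  expect_error(morphologyDelta(1, 1, af4(a1 = 0.4), 1), "sum to 1")
})

test_that("single-factor changes take the whole contribution share", {
  d <- morphologyDelta(1, 1, af4(), fl = 0.7)
  for (m in c("log", "one-at-a-time")) {
    r <- contributionShares(d, method = m)
    expect_equal(unname(r@shares["fl"]), 1)
    expect_equal(unname(r@shares[c("fn", "csa")]), c(0, 0))
  }
})

test_that("log shares reproduce the hand-computed 0.9/0.85/0.8 partition", {
  # factors fn = 0.9, csa term = 0.85, fl = 0.8 -> ratio 0.612
  d <- morphologyDelta(fn = 0.9,
                       csa = c("1" = 0.85, "2a" = 0.85, "2x" = 0.85,
                               "2b" = 0.85),
                       af = af4(), fl = 0.8)
  r <- contributionShares(d)
  expect_equal(r@massRatio, 0.612, tolerance = 1e-12)
  expect_equal(unname(r@shares["fn"]), 0.2145, tolerance = 1e-3)
  expect_equal(unname(r@shares["csa"]), 0.3310, tolerance = 1e-3)
  expect_equal(unname(r@shares["fl"]), 0.4545, tolerance = 1e-3)
  expect_equal(sum(r@shares), 1, tolerance = 1e-12)
})

test_that("one-at-a-time shares carry an interaction remainder", {
  d <- morphologyDelta(fn = 0.9, csa = setNames(rep(0.85, 4),
                                                c("1", "2a", "2x", "2b")),
                       af = af4(), fl = 0.8)
  r <- contributionShares(d, method = "one-at-a-time")
  expect_equal(unname(r@shares["fn"]), 0.1 / 0.388, tolerance = 1e-9)
  expect_equal(sum(r@shares) + r@remainder, 1, tolerance = 1e-12)
  # single-factor deficits overlap, so they overcount the joint deficit
  expect_lt(r@remainder, 0)
})

test_that("a unit ratio leaves the shares flagged undefined", {
  r <- contributionShares(morphologyDelta(1, 1, af4(), 1))
  expect_true(r@degenerate)
  expect_true(all(is.na(r@shares)))
})

test_that("log shares always sum to one and the ratio is factor-monotone", {
  set.seed(99)
  for (i in 1:50) {
    d <- morphologyDelta(fn = runif(1, 0.5, 1.4),
                         csa = setNames(runif(4, 0.5, 1.4),
                                        c("1", "2a", "2x", "2b")),
                         af = af4(), fl = runif(1, 0.5, 1.4))
    r <- contributionShares(d)
    if (!r@degenerate)
      expect_lt(abs(sum(r@shares) - 1), 1e-12)
  }
  base <- morphologyDelta(0.9, setNames(rep(0.9, 4), c("1", "2a", "2x", "2b")),
                          af4(), 0.9)
  for (up in c(1.05, 1.2)) {
    d2 <- base; d2@fn <- base@fn * up
    expect_gt(predictedMassRatio(d2), predictedMassRatio(base))
    d3 <- base; d3@fl <- base@fl * up
    expect_gt(predictedMassRatio(d3), predictedMassRatio(base))
    d4 <- base; d4@csa <- base@csa * up
    expect_gt(predictedMassRatio(d4), predictedMassRatio(base))
  }
})

test_that("noise-free cohorts give predicted == measured for every animal", {
  em <- defaultEffectModel(noiseCv = 0)
  co <- generateCohort(cohortDesign(nPerGroup = 3, seed = 17), em)
  d <- computeDeltas(co, af = em@af)
  expect_lt(max(abs(d$predicted_ratio - d$measured_ratio)), 1e-12)
})

test_that("missing-type CSA ratios fall back to no-change with a warning", {
  expect_warning(
    d <- morphologyDelta(fn = 0.9, csa = c("2a" = 0.8, "2x" = 1, "2b" = 1),
                         af = af4(), fl = 1),
    "treated as unchanged")
  expect_equal(unname(d@csa["1"]), 1)
})

test_that("regression validation matches the closed-form solution", {
  x <- c(0.10, 0.18, 0.25, 0.33, 0.41, 0.55)
  y <- c(0.14, 0.15, 0.30, 0.28, 0.45, 0.52)
  r <- validatePredictions(x, y)
  # normal equations
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  r2 <- slope^2 * var(x) / var(y)
  expect_equal(r@slope, slope, tolerance = 1e-10)
  expect_equal(r@intercept, intercept, tolerance = 1e-10)
  expect_equal(r@rSquared, r2, tolerance = 1e-10)
  expect_equal(r@n, 6L)
  # perfect agreement (suppress lm's perfect-fit note)
  rp <- suppressWarnings(validatePredictions(x, x))
  expect_equal(rp@slope, 1, tolerance = 1e-12)
  expect_equal(rp@intercept, 0, tolerance = 1e-12)
  expect_equal(rp@rSquared, 1, tolerance = 1e-12)
  expect_error(validatePredictions(c(1, 2), c(1, 2)), "at least 3")
  expect_error(validatePredictions(rep(0.5, 5), rnorm(5)), "zero variance")
})

test_that("group and animal decomposition modes agree without noise", {
  em <- defaultEffectModel(noiseCv = 0)
  co <- generateCohort(cohortDesign(genotype = "WT", nPerGroup = 3,
                                    seed = 18), em)
  a <- decomposeCohort(co, af = em@af, mode = "animal")
  g <- decomposeCohort(co, af = em@af, mode = "group")
  expect_equal(a$share_csa, g$share_csa, tolerance = 1e-9)
  expect_equal(a$mass_ratio, g$mass_ratio, tolerance = 1e-9)
})
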