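test_that("sham normalization divides by the sham-group mean", {
  expect_equal(normalizeToSham(9, c(10, 12, 14)), 0.75)
  sham <- c(10, 12, 14)
  expect_equal(mean(normalizeToSham(sham, sham)), 1)
  expect_equal(normalizeToSham(7, rep(7, 5)), 1)  # scale invariance
  expect_error(normalizeToSham(1, numeric(0)), "empty sham")
  expect_error(normalizeToSham(1, c(-2, 2)), "nonzero")
})

test_that("cohort-level sham normalization has unit sham means per cell", {
  co <- generateCohort(cohortDesign(genotype = "WT", nPerGroup = 5,
                                    seed = 51), defaultEffectModel())
  co <- shamNormalize(co, "ss_mass_mg")
  key <- interaction(co$sex, co$timepoint)
  for (cell in levels(key)) {
    sham <- co$ss_mass_mg_norm[key == cell & co$treatment == "SHM"]
    expect_equal(mean(sham), 1, tolerance = 1e-12)
  }
})

test_that("ratio normalization is a per-animal quotient", {
  expect_equal(ratioNormalize(50, 50), 1)
  expect_equal(ratioNormalize(45, 30), 1.5)
  expect_equal(ratioNormalize(45 * 3, 30 * 3), ratioNormalize(45, 30))
  expect_error(ratioNormalize(1, 0), "positive")
})

test_that("Sidak adjustment follows its formula and dominates raw p", {
  expect_equal(sidakAdjust(0.01, m = 5), 1 - 0.99^5)
  set.seed(1)
  p <- runif(20)
  expect_true(all(sidakAdjust(p) >= p))
  expect_true(all(diff(sidakAdjust(sort(p))) >= 0))     # order preserved
  expect_true(all(diff(p.adjust(sort(p), "BH")) >= 0))  # FDR step-up monotone
})

test_that("one balanced two-level factor reduces to the pooled t-test", {
  set.seed(52)
  d <- data.frame(g = rep(c("a", "b"), each = 8),
                  y = rnorm(16) + rep(c(0, 1), each = 8))
  res <- nwayAnova(d, "y", "g", pairwise = FALSE)
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(anovaEffects(res)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(anovaEffects(res)$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA p-values are invariant under affine response transforms", {
  co <- generateCohort(cohortDesign(genotype = "WT", timepoint = "W8",
                                    nPerGroup = 6, seed = 53),
                       defaultEffectModel())
  a <- nwayAnova(co, "ss_mass_mg", c("treatment", "sex"), pairwise = FALSE)
  co$shifted <- 3 * co$ss_mass_mg + 7
  b <- nwayAnova(co, "shifted", c("treatment", "sex"), pairwise = FALSE)
  expect_equal(anovaEffects(a)$p, anovaEffects(b)$p, tolerance = 1e-10)
})

test_that("pairwise contrasts are corrected and condition on other factors", {
  co <- generateCohort(cohortDesign(genotype = "WT", timepoint = "W8",
                                    nPerGroup = 6, seed = 54),
                       defaultEffectModel())
  res <- nwayAnova(co, "ss_mass_mg", c("treatment", "sex"), "sidak")
  pw <- pairwiseComparisons(res)
  expect_equal(nrow(pw), 2L)          # SHM-TEN within each sex
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-15))
  res3 <- nwayAnova(co, "ss_mass_mg", c("treatment", "sex"), "fdr")
  expect_true(all(pairwiseComparisons(res3)$correction == "fdr"))
})

test_that("empty design cells raise an error naming the cells", {
  co <- generateCohort(cohortDesign(genotype = "WT", timepoint = "W8",
                                    nPerGroup = 4, seed = 55),
                       defaultEffectModel())
  co <- co[!(co$sex == "F" & co$treatment == "TEN"), ]
  expect_error(nwayAnova(co, "ss_mass_mg", c("treatment", "sex")),
               "TEN/F|F/TEN|inestimable")
})

test_that("Shapiro-Wilk wrapper guards its domain", {
  set.seed(56)
  sw <- shapiroWilk(rnorm(50))
  expect_true(sw$W > 0.9 && sw$p >= 0)
  # strongly bimodal sample: two separated point masses plus a whisker
  bim <- c(rnorm(25, 0, 0.05), rnorm(25, 10, 0.05))
  expect_lt(shapiroWilk(bim)$p, 0.05)
  expect_error(shapiroWilk(rep(1, 10)), "identical")
  expect_error(shapiroWilk(c(1, 2)), "sample size")
})

test_that("simulated power rises with effect size at fixed n", {
  set.seed(57)
  power <- vapply(c(0, 0.8, 1.8), function(eff) {
    rej <- vapply(1:120, function(i) {
      d <- data.frame(g = rep(c("a", "b"), each = 6),
                      y = rnorm(12) + rep(c(0, eff), each = 6))
      anovaEffects(nwayAnova(d, "y", "g", pairwise = FALSE))$p < 0.05
    }, logical(1))
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(power) > 0))
})
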