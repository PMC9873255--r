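test_that("identity effects with zero noise reproduce the sham means exactly", {
  co <- generateCohort(cohortDesign(genotype = "WT", nPerGroup = 3, seed = 1),
                       nullEffectModel())
  key <- interaction(co$sex, co$timepoint)
  for (cell in levels(key)) {
    sham <- co[key == cell & co$treatment == "SHM", ]
    ten <- co[key == cell & co$treatment == "TEN", ]
    for (col in c("ss_mass_mg", "is_mass_mg", "fiber_number", "csa_2b",
                  "muscle_length_cm", "fiber_length_cm"))
      expect_equal(ten[[col]], rep(mean(sham[[col]]), nrow(ten)),
                   tolerance = 1e-12)
  }
})

test_that("noise-free mass ratio equals the configured cylinder product", {
  # dFN x (sum AF dCSA) x dFL = 0.9 x (0.5 + 0.5 x 0.7) x 0.8 = 0.612
  em <- flatEffectModel(fn = 0.9, fl = 0.8,
                        csa = c("1" = 1, "2a" = 1, "2x" = 1, "2b" = 0.7),
                        af = c("1" = 0.1, "2a" = 0.2, "2x" = 0.2,
                               "2b" = 0.5))
  co <- generateCohort(cohortDesign(genotype = "WT", nPerGroup = 4, seed = 9),
                       em)
  key <- interaction(co$sex, co$timepoint)
  for (cell in levels(key)) {
    sham <- mean(co$ss_mass_mg[key == cell & co$treatment == "SHM"])
    ratios <- co$ss_mass_mg[key == cell & co$treatment == "TEN"] / sham
    expect_equal(ratios, rep(0.612, length(ratios)), tolerance = 1e-12)
  }
  expect_equal(co$true_mass_ratio[co$treatment == "TEN"][1], 0.612,
               tolerance = 1e-12)
})

test_that("cohort generation is seed-deterministic", {
  d <- cohortDesign(genotype = "WT", timepoint = "W8", nPerGroup = 4,
                    seed = 7)
  em <- defaultEffectModel()
  expect_identical(generateCohort(d, em), generateCohort(d, em))
  d2 <- d
  d2@seed <- 8L
  expect_false(isTRUE(all.equal(generateCohort(d, em)$ss_mass_mg,
                                generateCohort(d2, em)$ss_mass_mg)))
})

test_that("lognormal noise keeps measurements positive and near unit mean", {
  co <- generateCohort(cohortDesign(genotype = "WT", timepoint = "W8",
                                    nPerGroup = 200, seed = 3),
                       nullEffectModel(noiseCv = 0.2))
  expect_true(all(co$ss_mass_mg > 0))
  m <- co[co$sex == "M", ]
  expect_equal(mean(m$true_fn_ratio), 1, tolerance = 0.05)
  expect_equal(sd(m$true_fn_ratio) / mean(m$true_fn_ratio), 0.2,
               tolerance = 0.25)
})

test_that("invalid designs and incomplete effect models are rejected", {
  expect_error(cohortDesign(sex = character(0)), "no levels")
  expect_error(cohortDesign(genotype = "XX"), "outside")
  em <- defaultEffectModel()
  em@effects <- em@effects[em@effects$timepoint != "W8", ]
  expect_error(
    generateCohort(cohortDesign(genotype = "WT", nPerGroup = 2, seed = 1),
                   em),
    "lacks an effects row")
})
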