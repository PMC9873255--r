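test_that("a tiny noise-free section is an exact ribbon tessellation", {
  sec <- generateSection(sectionSpec(imageSize = 96, fiberCount = 3,
                                     seed = 11))
  truth <- sec$truth
  expect_equal(nFibers(truth), 3L)
  lab <- fiberLabels(truth)
  # regions disjoint by construction of a label image; all three nonempty
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), 1:3)
  # laminin is bright exactly on the ribbon complement of the fiber union
  lam <- getChannel(sec$image, "laminin")
  ribbon <- tissueMask(truth) & lab == 0L
  expect_identical(lam > 0.5, ribbon)
  # areas account for all tissue outside the ribbon
  expect_equal(sum(fiberAreas(truth)),
               (sum(tissueMask(truth)) - sum(ribbon)) *
                 pixelSize(truth)^2)
})

test_that("zero pathology rates yield all-false ground-truth flags", {
  sec <- generateSection(sectionSpec(imageSize = 128, fiberCount = 8,
                                     seed = 2, centralNucleiRate = 0,
                                     punctaRate = 0))
  expect_false(any(sec$truth@centralNucleus))
  expect_false(any(sec$truth@punctum))
  expect_equal(nrow(sec$truth@puncta), 0L)
})

test_that("red stain is painted to the requested area fraction", {
  sec <- generateSection(sectionSpec(imageSize = 256, fiberCount = 30,
                                     seed = 4, fatFraction = 0.10))
  truth <- sec$truth
  frac <- sum(truth@redMask & tissueMask(truth)) / sum(tissueMask(truth))
  # one painted blob (radius 3, 29 px) of overshoot at most
  expect_gte(frac, 0.10)
  expect_lte(frac, 0.10 + 29 / sum(tissueMask(truth)) + 1e-12)
})

test_that("section generation is seed-deterministic", {
  sp <- sectionSpec(imageSize = 128, fiberCount = 10, seed = 21,
                    centralNucleiRate = 0.3, noiseSd = 0.05)
  a <- generateSection(sp)
  b <- generateSection(sp)
  expect_identical(a$image@channels, b$image@channels)
  expect_identical(a$truth@labels, b$truth@labels)
  sp2 <- sp
  sp2@seed <- 22L
  c <- generateSection(sp2)
  expect_false(identical(a$truth@labels, c$truth@labels))
})

test_that("infeasible packing is reported", {
  expect_error(generateSection(sectionSpec(imageSize = 64,
                                           fiberCount = 500, seed = 1)),
               "infeasible packing")
})

test_that("ground-truth polygons are one convex hull per fiber", {
  sec <- generateSection(sectionSpec(imageSize = 96, fiberCount = 4,
                                     seed = 5))
  polys <- fiberPolygons(sec$truth)
  expect_length(polys, 4L)
  expect_true(all(vapply(polys, nrow, integer(1)) >= 3L))
})

test_that("flagged structures lie inside their fiber polygons", {
  sec <- generateSection(sectionSpec(imageSize = 256, fiberCount = 40,
                                     seed = 6, centralNucleiRate = 0.4,
                                     punctaRate = 0.3))
  truth <- sec$truth
  nuc <- truth@nuclei[truth@nuclei$central, ]
  expect_gt(nrow(nuc), 0L)
  expect_true(all(truth@labels[cbind(nuc$row, nuc$col)] == nuc$fiber))
  expect_true(all(truth@labels[cbind(truth@puncta$row, truth@puncta$col)] ==
                    truth@puncta$fiber))
})
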