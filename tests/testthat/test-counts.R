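test_that("pathology and cell counts recover generator ground truth exactly", {
  sec <- generateSection(sectionSpec(imageSize = 320, fiberCount = 60,
                                     seed = 31, centralNucleiRate = 0.25,
                                     punctaRate = 0.15,
                                     interstitialCellRate = 0.4,
                                     sublaminarCellRate = 0.25))
  truth <- sec$truth
  fs <- segmentFibers(sec$image)
  expect_equal(nFibers(fs), nFibers(truth))
  expect_equal(countCentralNuclei(fs, sec$image),
               100 * mean(truth@centralNucleus))
  expect_equal(countBasophilicPuncta(fs, sec$image),
               100 * mean(truth@punctum))
  expect_equal(countMarkerCells(fs, sec$image, "pdgfra", "interstitial"),
               sum(truth@cells$compartment == "interstitial") /
                 nFibers(truth))
  expect_equal(countMarkerCells(fs, sec$image, "pax7", "sublaminar"),
               sum(truth@cells$compartment == "sublaminar") /
                 nFibers(truth))
})

test_that("zero rates give zero counts", {
  sec <- generateSection(sectionSpec(imageSize = 160, fiberCount = 10,
                                     seed = 32))
  fs <- segmentFibers(sec$image)
  expect_equal(countCentralNuclei(fs, sec$image), 0)
  expect_equal(countBasophilicPuncta(fs, sec$image), 0)
  expect_equal(countMarkerCells(fs, sec$image, "pdgfra", "interstitial"), 0)
  expect_equal(countMarkerCells(fs, sec$image, "pax7", "sublaminar"), 0)
})

test_that("counting rules respect compartment geometry", {
  # one fiber; structures drawn by hand
  img <- toySection(n = 40, fibers = list(c(r1 = 8, r2 = 32, c1 = 8,
                                            c2 = 32)))
  dapi <- img@channels$dapi
  hema <- img@channels$hematoxylin
  # nucleus straddling the boundary: centroid on the laminin ribbon
  dapi[4:6, 18:20] <- 0.9
  hema[4:6, 18:20] <- 0.9
  # deep central nucleus
  dapi[19:21, 19:21] <- 0.9
  hema[19:21, 19:21] <- 0.9
  # hematoxylin-only punctum (autophagic-vesicle-like), deep inside
  hema[26:27, 26:27] <- 0.9
  img@channels$dapi <- dapi
  img@channels$hematoxylin <- hema
  # marker blob dead-center: neither interstitial nor sublaminar
  marker <- matrix(0.05, 40, 40)
  marker[20, 20] <- 0.9
  img@channels$pdgfra <- marker
  fs <- segmentFibers(img, minArea = 10)
  expect_equal(nFibers(fs), 1L)
  expect_equal(countCentralNuclei(fs, img), 100)   # the deep nucleus only
  expect_equal(countBasophilicPuncta(fs, img), 100)
  expect_equal(countMarkerCells(fs, img, "pdgfra", "interstitial"), 0)
  expect_equal(countMarkerCells(fs, img, "pdgfra", "sublaminar"), 0)
})

test_that("a dual-positive structure is a nucleus, never a punctum", {
  img <- toySection(n = 40, fibers = list(c(r1 = 8, r2 = 32, c1 = 8,
                                            c2 = 32)))
  img@channels$dapi[19:21, 19:21] <- 0.9
  img@channels$hematoxylin[19:21, 19:21] <- 0.9
  fs <- segmentFibers(img, minArea = 10)
  expect_equal(countCentralNuclei(fs, img), 100)
  expect_equal(countBasophilicPuncta(fs, img), 0)
})

test_that("whole-section metrics bundle is internally consistent", {
  sec <- generateSection(sectionSpec(imageSize = 256, fiberCount = 40,
                                     seed = 33, centralNucleiRate = 0.2,
                                     fatFraction = 0.08))
  m <- sectionMetrics(sec$image)
  expect_equal(m$fiber_number, 40L)
  expect_equal(sum(m$type_fractions), 1)
  expect_true(m$central_nuclei_pct >= 0 && m$central_nuclei_pct <= 100)
  expect_equal(m$red_area_fraction, 0.08, tolerance = 0.01)
  expect_equal(m$fiber_number, nFibers(m$fibers))
})
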