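test_that("noise-free sections segment to the exact ground-truth fibers", {
  sec <- generateSection(sectionSpec(imageSize = 96, fiberCount = 3,
                                     seed = 11))
  fs <- segmentFibers(sec$image)
  expect_equal(nFibers(fs), 3L)
  m <- matchFibers(fs, sec$truth)
  expect_true(all(abs(m$area_um2 / m$truth_area_um2 - 1) <= 0.05))

  sec2 <- generateSection(sectionSpec(imageSize = 448, fiberCount = 120,
                                      seed = 12))
  expect_equal(nFibers(segmentFibers(sec2$image)), 120L)
})

test_that("a flat laminin channel is a degenerate input", {
  img <- SectionImage(list(laminin = matrix(0.3, 32, 32)), pixelSize = 1)
  expect_error(segmentFibers(img), "degenerate")
})

test_that("particle filters remove small and border-touching regions", {
  img <- toySection(n = 40,
                    fibers = list(c(r1 = 6, r2 = 16, c1 = 6, c2 = 16),
                                  c(r1 = 24, r2 = 26, c1 = 24, c2 = 26),
                                  c(r1 = 1, r2 = 10, c1 = 30, c2 = 40)))
  # 3x3 region falls below 100 um^2 at 2 um/px; third region touches border
  img@pixelSize <- 2
  fs <- segmentFibers(img, minArea = 100)
  expect_equal(nFibers(fs), 1L)
  expect_false(any(fiberTable(fs)$touches_border))
  fs2 <- segmentFibers(img, minArea = 0, excludeBorder = FALSE)
  expect_equal(nFibers(fs2), 3L)
})

test_that("MHC-dark fibers type as 2x and multi-positive fibers flag hybrid", {
  img <- toySection(
    fiberValues = list(
      c(mhc2a = 0.7, mhc2b = 0.9),  # double positive, 2b stronger
      c()))                         # dark in all three channels
  fs <- assignFiberTypes(segmentFibers(img, minArea = 10), img)
  tab <- fiberTable(fs)
  # fibers are labeled in raster order: fiber 1 is the upper-left block
  expect_setequal(tab$type, c("2b", "2x"))
  expect_equal(tab$hybrid[tab$type == "2b"], TRUE)
  expect_equal(tab$hybrid[tab$type == "2x"], FALSE)
})

test_that("fiber typing recovers all ground-truth types without noise", {
  sec <- generateSection(sectionSpec(imageSize = 256, fiberCount = 50,
                                     seed = 13))
  fs <- assignFiberTypes(segmentFibers(sec$image), sec$image)
  m <- matchFibers(fs, sec$truth)
  expect_equal(fiberTypes(fs)[m$id], fiberTypes(sec$truth)[m$truth_id])
})

test_that("CSA statistics report per-type means and missing types as NA", {
  img <- toySection(
    fiberValues = list(c(mhc2b = 0.9), c(mhc2b = 0.9)))
  fs <- assignFiberTypes(segmentFibers(img, minArea = 10), img)
  # both fibers are 11 x 11 px = 121 um^2 at 1 um/px
  st <- csaStatistics(fs, binWidth = 200)
  m <- st$means
  expect_equal(m$mean_csa[m$type == "2b"], 121)
  expect_equal(m$n[m$type == "2b"], 2L)
  expect_true(is.na(m$mean_csa[m$type == "1"]))
  expect_null(st$histograms[["1"]])
  expect_equal(sum(st$histograms[["2b"]]$counts > 0), 1L)
  expect_equal(sum(st$histograms[["2b"]]$counts), 2L)
})

test_that("per-type CSA means track the generator ground truth", {
  sec <- generateSection(sectionSpec(imageSize = 448, fiberCount = 120,
                                     seed = 14))
  fs <- assignFiberTypes(segmentFibers(sec$image), sec$image)
  st <- csaStatistics(fs)
  truthMeans <- tapply(fiberAreas(sec$truth), fiberTypes(sec$truth), mean)
  for (t in names(truthMeans)) {
    got <- st$means$mean_csa[st$means$type == t]
    expect_equal(got, unname(truthMeans[t]), tolerance = 0.05)
  }
})

test_that("area fraction is 0 for blank channels and ~1 for full ones", {
  n <- 64
  tis <- matrix(TRUE, n, n)
  img <- SectionImage(list(redstain = matrix(0.05, n, n)), pixelSize = 1,
                      tissueMask = tis)
  expect_equal(areaFraction(img, "redstain"), 0)
  half <- row(matrix(0, n, n)) <= n / 2
  two <- matrix(0.05, n, n)
  two[half] <- 0.9
  img2 <- SectionImage(list(redstain = two), pixelSize = 1,
                       tissueMask = half)
  expect_equal(areaFraction(img2, "redstain"), 1)
  expect_error(areaFraction(img, "redstain",
                            tissue = matrix(FALSE, n, n)), "empty tissue")
})

test_that("area fraction is monotone in the painted target fraction", {
  got <- vapply(c(0.05, 0.15, 0.30), function(f) {
    sec <- generateSection(sectionSpec(imageSize = 192, fiberCount = 15,
                                       seed = 8, fatFraction = f))
    areaFraction(sec$image)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_equal(got[2], 0.15, tolerance = 0.02)
})
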