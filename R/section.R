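# -- small raster helpers -----------------------------------------------------

# Offsets of a filled disk of the given pixel radius, as a k x 2 matrix.
.diskOffsets <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  as.matrix(d[d$dr^2 + d$dc^2 <= radius^2, ])
}

# Stamp a constant value over offset neighbourhoods of the given centers.
.stamp <- function(m, centers, offsets, value) {
  if (nrow(centers) == 0L) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  for (i in seq_len(nrow(centers))) {
    r <- centers[i, 1L] + offsets[, 1L]
    c <- centers[i, 2L] + offsets[, 2L]
    ok <- r >= 1L & r <= n1 & c >= 1L & c <= n2
    m[cbind(r[ok], c[ok])] <- value
  }
  m
}

# Greedily pick up to n points from candidate (row, col) positions, keeping a
# minimum separation from each other and from 'avoid'. Returns a k x 2 matrix.
.placePoints <- function(cand, n, minSep, avoid = NULL) {
  out <- matrix(numeric(0), 0L, 2L)
  if (n == 0L || nrow(cand) == 0L) return(out)
  sep2 <- minSep^2
  tries <- 0L
  maxTries <- 80L * n + 200L
  while (nrow(out) < n && tries < maxTries) {
    tries <- tries + 1L
    p <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
    others <- rbind(out, avoid)
    if (nrow(others) == 0L ||
        min((others[, 1L] - p[1L])^2 + (others[, 2L] - p[2L])^2) >= sep2) {
      out <- rbind(out, p)
    }
  }
  out
}

# Poisson-disk ("dart throwing") centroid sampling inside a disk.
.poissonDisk <- function(n, center, radius, minDist) {
  pts <- matrix(numeric(0), 0L, 2L)
  tries <- 0L
  maxTries <- 300L * n
  while (nrow(pts) < n && tries < maxTries) {
    tries <- tries + 1L
    a <- runif(1L, 0, 2 * pi)
    r <- radius * sqrt(runif(1L))
    p <- c(center + r * sin(a), center + r * cos(a))
    if (nrow(pts) == 0L ||
        min((pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2) >= minDist^2) {
      pts <- rbind(pts, p)
    }
  }
  if (nrow(pts) < n)
    stop("infeasible packing: cannot place ", n, " fibers in a ",
         round(2 * radius), " px tissue disk", call. = FALSE)
  pts
}

#' Generate a synthetic stained muscle section with ground truth
#'
#' Builds a section by bounded random tessellation: Poisson-disk fiber
#' centroids inside a disk-shaped tissue mask, Voronoi cells shrunk by the
#' boundary ribbon width to leave a bright laminin network between fibers.
#' Each fiber receives one myosin-heavy-chain type (type assignment is
#' biased by cell size toward the configured per-type CSA targets); MHC
#' channels are bright inside fibers of the matching type and type-2x
#' fibers stay dark in all three. DAPI nuclei are placed on fiber
#' boundaries, plus central nuclei in a `centralNucleiRate` fraction of
#' fibers; hematoxylin-positive/DAPI-negative puncta in a `punctaRate`
#' fraction; the red-stain channel is painted to the requested fat plus
#' fibrosis area fraction; PDGFRa-like interstitial and Pax7-like
#' sublaminar marker cells are dropped at their per-fiber rates. Gaussian
#' blur and additive noise are applied last; the returned
#' [SectionGroundTruth-class] records everything pre-noise.
#'
#' @param spec a [SectionSpec-class].
#' @return list with elements `image` ([SectionImage-class]) and `truth`
#'   ([SectionGroundTruth-class]).
#' @examples
#' sec <- generateSection(sectionSpec(imageSize = 192, fiberCount = 20,
#'                                    seed = 2))
#' sec$truth
#' @export
generateSection <- function(spec) {
  validObject(spec)
  n <- spec@imageSize
  w <- spec@ribbonWidth
  px <- spec@pixelSize
  .withSeed(spec@seed, {
    c0 <- (n + 1) / 2
    R <- 0.47 * n
    rr <- row(matrix(0, n, n))
    cc <- col(matrix(0, n, n))
    dCenter <- sqrt((rr - c0)^2 + (cc - c0)^2)
    tissue <- dCenter <= R

    k <- spec@fiberCount
    rCent <- R - w - 2
    meanCell <- pi * rCent^2 / k
    cent <- .poissonDisk(k, c0, rCent, minDist = 0.70 * sqrt(meanCell))

    # nearest and second-nearest centroid per pixel (squared distances)
    best1 <- matrix(Inf, n, n); best2 <- matrix(Inf, n, n)
    idx1 <- matrix(0L, n, n)
    for (i in seq_len(k)) {
      d2 <- (rr - cent[i, 1L])^2 + (cc - cent[i, 2L])^2
      closer <- d2 < best1
      best2[closer] <- best1[closer]
      best1[closer] <- d2[closer]
      idx1[closer] <- i
      mid <- !closer & d2 < best2
      best2[mid] <- d2[mid]
    }
    ribbon <- (sqrt(best2) - sqrt(best1)) < w | dCenter > (R - w)
    labels <- ifelse(tissue & !ribbon, idx1, 0L)
    counts <- tabulate(labels[labels > 0L], nbins = k)
    if (any(counts == 0L))
      stop("infeasible packing: ", sum(counts == 0L),
           " fiber cell(s) vanished after ribbon shrinkage", call. = FALSE)
    areas <- counts * px^2

    # size-biased type assignment: P(type | area) ~ fraction * N(mean, sd)
    types <- vapply(seq_len(k), function(i) {
      lik <- spec@typeFractions *
        dnorm(areas[i], spec@typeCsaMean, pmax(spec@typeCsaSd, 1e-6))
      if (sum(lik) <= 0) lik <- spec@typeFractions
      sample(FIBER_TYPES, 1L, prob = lik)
    }, character(1))

    bg <- 0.05; hi <- 0.85
    blank <- matrix(bg, n, n)
    laminin <- blank; laminin[tissue & ribbon] <- hi
    mhc <- list()
    for (tp in names(MHC_ROLES)) {
      m <- blank
      m[labels > 0L & matrix(types[pmax(labels, 1L)] == tp, n, n)] <- hi
      mhc[[MHC_ROLES[[tp]]]] <- m
    }

    distIn <- .distanceIntoMask(labels > 0L)
    fiberIdx <- which(labels > 0L)

    # nuclei: ~1.2 per fiber on boundaries, plus flagged central nuclei
    nucOff <- .diskOffsets(2L)
    ribbonRC <- which(tissue & ribbon, arr.ind = TRUE)
    bnd <- .placePoints(ribbonRC, round(1.2 * k), minSep = 7)
    centralFlag <- runif(k) < spec@centralNucleiRate
    centRC <- matrix(numeric(0), 0L, 2L)
    centFiber <- integer(0)
    for (f in which(centralFlag)) {
      cand <- which(labels == f & distIn >= 6, arr.ind = TRUE)
      p <- .placePoints(cand, 1L, minSep = 7, avoid = rbind(bnd, centRC))
      if (nrow(p) == 1L) {
        centRC <- rbind(centRC, p)
        centFiber <- c(centFiber, f)
      } else {
        centralFlag[f] <- FALSE  # fiber too small to host a central nucleus
      }
    }
    dapi <- blank
    dapi <- .stamp(dapi, bnd, nucOff, 0.9)
    dapi <- .stamp(dapi, centRC, nucOff, 0.9)
    hema <- blank
    hema <- .stamp(hema, bnd, nucOff, 0.9)
    hema <- .stamp(hema, centRC, nucOff, 0.9)

    # basophilic puncta: hematoxylin-only, away from all nuclei
    plusOff <- .diskOffsets(1L)
    punctumFlag <- runif(k) < spec@punctaRate
    puncRC <- matrix(numeric(0), 0L, 2L)
    puncFiber <- integer(0)
    allNuc <- rbind(bnd, centRC)
    for (f in which(punctumFlag)) {
      cand <- which(labels == f & distIn >= 4, arr.ind = TRUE)
      p <- .placePoints(cand, 1L, minSep = 8, avoid = rbind(allNuc, puncRC))
      if (nrow(p) == 1L) {
        puncRC <- rbind(puncRC, p)
        puncFiber <- c(puncFiber, f)
      } else {
        punctumFlag[f] <- FALSE
      }
    }
    hema <- .stamp(hema, puncRC, plusOff, 0.9)

    # red stain painted to the fat + fibrosis target fraction of tissue
    redTarget <- spec@fatFraction + spec@fibrosisFraction
    redMask <- matrix(FALSE, n, n)
    if (redTarget > 0) {
      tissueN <- sum(tissue)
      tissueRC <- which(tissue, arr.ind = TRUE)
      blobOff <- .diskOffsets(3L)
      guard <- 0L
      while (sum(redMask & tissue) < redTarget * tissueN &&
             guard < 50L * tissueN) {
        guard <- guard + 1L
        p <- tissueRC[sample.int(nrow(tissueRC), 1L), , drop = FALSE]
        redMask <- .stamp(redMask, p, blobOff, TRUE)
      }
      redMask <- redMask & tissue
    }
    red <- blank; red[redMask] <- 0.9

    # marker cells: interstitial (FAP-like) on ribbons, sublaminar
    # (satellite-cell-like) just beneath the fiber boundary
    nFap <- rpois(1L, spec@interstitialCellRate * k)
    innerRibbon <- which(tissue & ribbon & dCenter <= (R - w), arr.ind = TRUE)
    fapRC <- .placePoints(innerRibbon, nFap, minSep = 6)
    nSc <- rpois(1L, spec@sublaminarCellRate * k)
    subl <- which(labels > 0L & distIn >= 1 & distIn < 2, arr.ind = TRUE)
    scRC <- .placePoints(subl, nSc, minSep = 6)
    pdgfra <- .stamp(blank, fapRC, plusOff, 0.9)
    pax7 <- .stamp(blank, scRC, plusOff, 0.9)

    channels <- c(list(laminin = laminin), mhc,
                  list(dapi = dapi, hematoxylin = hema, redstain = red,
                       pdgfra = pdgfra, pax7 = pax7))

    # ground truth is frozen before degradation
    nuclei <- data.frame(
      row = c(bnd[, 1L], centRC[, 1L]), col = c(bnd[, 2L], centRC[, 2L]),
      fiber = c(rep(0L, nrow(bnd)), centFiber),
      central = c(rep(FALSE, nrow(bnd)), rep(TRUE, nrow(centRC))))
    puncta <- data.frame(row = puncRC[, 1L], col = puncRC[, 2L],
                         fiber = puncFiber)
    cells <- data.frame(
      marker = c(rep("pdgfra", nrow(fapRC)), rep("pax7", nrow(scRC))),
      compartment = c(rep("interstitial", nrow(fapRC)),
                      rep("sublaminar", nrow(scRC))),
      row = c(fapRC[, 1L], scRC[, 1L]), col = c(fapRC[, 2L], scRC[, 2L]),
      stringsAsFactors = FALSE)
    truth <- new("SectionGroundTruth", labels = labels, fiberTypes = types,
                 fiberAreas = areas, centralNucleus = centralFlag,
                 punctum = punctumFlag, nuclei = nuclei, puncta = puncta,
                 cells = cells, redMask = redMask, tissueMask = tissue,
                 pixelSize = px)

    if (spec@blurSd > 0)
      channels <- lapply(channels, function(m)
        as.matrix(EBImage::gblur(EBImage::Image(m), sigma = spec@blurSd)))
    if (spec@noiseSd > 0)
      channels <- lapply(channels, function(m)
        pmin(pmax(m + rnorm(length(m), sd = spec@noiseSd), 0), 1))

    list(image = SectionImage(channels, pixelSize = px, tissueMask = tissue),
         truth = truth)
  })
}

# Euclidean distance of each in-mask pixel to the nearest out-of-mask pixel.
.distanceIntoMask <- function(mask) {
  as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
}

#' Convex-hull polygons of ground-truth fibers
#'
#' Convenience view of the tessellation: one convex polygon (pixel-center
#' coordinates, 0-based, row-major convention) per fiber. Cells of a
#' Voronoi tessellation clipped to a disk are convex, so the hull is the
#' fiber outline up to pixel quantization.
#'
#' @param truth a [SectionGroundTruth-class].
#' @return list of two-column matrices (`row`, `col`), one per fiber.
#' @export
fiberPolygons <- function(truth) {
  stopifnot(is(truth, "SectionGroundTruth"))
  lapply(seq_len(nFibers(truth)), function(f) {
    rc <- which(truth@labels == f, arr.ind = TRUE) - 1L
    rc[grDevices::chull(rc), , drop = FALSE]
  })
}
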