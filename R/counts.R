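# Binarize a channel for blob detection; a flat channel means no signal.
.binMask <- function(image, role) {
  b <- .huangBinarize(getChannel(image, role))
  if (is.null(b)) {
    d <- dim(image)
    matrix(FALSE, d[1L], d[2L])
  } else b$mask
}

# Label a binary mask and return integer centroid pixels per blob.
.blobCentroids <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  k <- max(lab)
  if (k == 0L)
    return(list(labels = lab,
                centroids = matrix(integer(0), 0L, 2L)))
  rc <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  cr <- round(tapply(rc[, 1L], l, mean))
  cl <- round(tapply(rc[, 2L], l, mean))
  list(labels = lab, centroids = cbind(row = as.integer(cr),
                                       col = as.integer(cl)))
}

# Mean of a binary mask over each blob of a label image.
.blobMean <- function(lab, mask) {
  sel <- lab > 0L
  as.numeric(tapply(mask[sel], lab[sel], mean))
}

#' Count fibers with central nuclei
#'
#' A nucleus is a connected blob positive in both the DAPI and hematoxylin
#' channels. It counts as central when its centroid lies inside a fiber
#' eroded by `margin` pixels — nuclei adjacent to the laminin boundary
#' (the normal subsarcolemmal position) fail this test. The result is the
#' percentage of fibers containing at least one central nucleus.
#'
#' @param fibers a [FiberSet-class].
#' @param image the matching [SectionImage-class] with `dapi` and
#'   `hematoxylin` channels.
#' @param margin erosion margin in pixels (default 2).
#' @return percent of fibers, in \[0, 100\].
#' @export
countCentralNuclei <- function(fibers, image, margin = 2) {
  .countIntrafiber(fibers, image, margin, puncta = FALSE)
}

#' Count fibers with basophilic puncta
#'
#' Basophilic puncta are hematoxylin-positive but DAPI-negative structures
#' (in chronic tenotomy they mark accumulated autophagic vesicles). Blobs
#' positive in both channels are nuclei and are excluded. Counting rule
#' and output are as in [countCentralNuclei()].
#'
#' @inheritParams countCentralNuclei
#' @return percent of fibers, in \[0, 100\].
#' @export
countBasophilicPuncta <- function(fibers, image, margin = 2) {
  .countIntrafiber(fibers, image, margin, puncta = TRUE)
}

.countIntrafiber <- function(fibers, image, margin, puncta) {
  stopifnot(is(fibers, "FiberSet"), is(image, "SectionImage"))
  for (ch in c("dapi", "hematoxylin"))
    if (!ch %in% channelNames(image))
      stop("missing channel: ", ch, call. = FALSE)
  k <- nFibers(fibers)
  if (k == 0L) stop("no fibers to score", call. = FALSE)
  dapiBin <- .binMask(image, "dapi")
  hemaBin <- .binMask(image, "hematoxylin")
  # nuclei are DAPI blobs; puncta are hematoxylin blobs without DAPI
  blobs <- .blobCentroids(if (puncta) hemaBin else dapiBin)
  if (nrow(blobs$centroids) == 0L) return(0)
  other <- .blobMean(blobs$labels, if (puncta) dapiBin else hemaBin)
  wanted <- if (puncta) other < 0.5 else other >= 0.5
  lab <- fibers@labels
  distIn <- .distanceIntoMask(lab > 0L)
  ctr <- blobs$centroids
  inside <- lab[ctr] > 0L & distIn[ctr] > margin & wanted
  hitFibers <- unique(lab[ctr[inside, , drop = FALSE]])
  100 * length(hitFibers) / k
}

#' Count marker-positive cells by compartment
#'
#' Classifies marker-channel blobs by centroid position relative to the
#' segmented fibers: `interstitial` cells (FAP-like, e.g. PDGFRa) lie
#' outside every fiber, in the laminin network between them; `sublaminar`
#' cells (satellite-cell-like, e.g. Pax7) lie inside a fiber within
#' `margin` pixels of its boundary. Blobs deep inside a fiber fall in
#' neither compartment.
#'
#' @param fibers a [FiberSet-class].
#' @param image the matching [SectionImage-class].
#' @param marker marker channel role (e.g. `"pdgfra"`, `"pax7"`).
#' @param compartment `"interstitial"` or `"sublaminar"`.
#' @param margin sublaminar depth in pixels (default 2).
#' @return cells per fiber (count / fiber number).
#' @export
countMarkerCells <- function(fibers, image, marker,
                             compartment = c("interstitial", "sublaminar"),
                             margin = 2) {
  stopifnot(is(fibers, "FiberSet"), is(image, "SectionImage"))
  compartment <- match.arg(compartment)
  if (!marker %in% channelNames(image))
    stop("missing channel: ", marker, call. = FALSE)
  k <- nFibers(fibers)
  if (k == 0L) stop("no fibers to normalize against", call. = FALSE)
  blobs <- .blobCentroids(.binMask(image, marker))
  if (nrow(blobs$centroids) == 0L) return(0)
  lab <- fibers@labels
  distIn <- .distanceIntoMask(lab > 0L)
  ctr <- blobs$centroids
  inFiber <- lab[ctr] > 0L
  hit <- if (compartment == "interstitial") {
    !inFiber
  } else {
    inFiber & distIn[ctr] <= margin
  }
  sum(hit) / k
}

#' Whole-section morphometry summary
#'
#' Runs the full quantification chain on one section: fiber count,
#' per-type CSA statistics and type fractions, central-nuclei and puncta
#' percentages, red-stain area fraction, and marker-cell densities.
#'
#' @param image a [SectionImage-class].
#' @param minArea,maxArea,excludeBorder passed to [segmentFibers()].
#' @param margin passed to the counting functions.
#' @param binWidth passed to [csaStatistics()].
#' @return list with `fiber_number`, `csa` (see [csaStatistics()]),
#'   `type_fractions`, `central_nuclei_pct`, `puncta_pct`,
#'   `red_area_fraction`, `faps_per_fiber`, `scs_per_fiber`, and the
#'   [FiberSet-class] as `fibers`.
#' @export
sectionMetrics <- function(image, minArea = 100, maxArea = Inf,
                           excludeBorder = TRUE, margin = 2,
                           binWidth = 200) {
  fibers <- segmentFibers(image, minArea, maxArea, excludeBorder)
  fibers <- assignFiberTypes(fibers, image)
  k <- nFibers(fibers)
  csa <- if (k > 0L) csaStatistics(fibers, binWidth) else NULL
  tf <- if (k > 0L) {
    tt <- table(factor(fiberTypes(fibers), levels = FIBER_TYPES))
    as.numeric(tt) / k
  } else rep(NA_real_, 4L)
  names(tf) <- FIBER_TYPES
  list(
    fiber_number = k,
    csa = csa,
    type_fractions = tf,
    central_nuclei_pct = if (k) countCentralNuclei(fibers, image, margin)
                         else NA_real_,
    puncta_pct = if (k) countBasophilicPuncta(fibers, image, margin)
                 else NA_real_,
    red_area_fraction = if ("redstain" %in% channelNames(image))
      areaFraction(image, "redstain") else NA_real_,
    faps_per_fiber = if (k && "pdgfra" %in% channelNames(image))
      countMarkerCells(fibers, image, "pdgfra", "interstitial", margin)
      else NA_real_,
    scs_per_fiber = if (k && "pax7" %in% channelNames(image))
      countMarkerCells(fibers, image, "pax7", "sublaminar", margin)
      else NA_real_,
    fibers = fibers
  )
}
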