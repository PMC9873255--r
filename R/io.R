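#' Write and read section images as multi-page TIFF
#'
#' Channels are written as 16-bit pages of one TIFF in a fixed order; the
#' channel roles and pixel size go to a JSON descriptor next to the image
#' (`<path>.json`). Intensities are clipped to \[0, 1\] for storage. The
#' tissue mask is not persisted; resupply it on read if needed.
#'
#' @param image a [SectionImage-class].
#' @param path TIFF file path.
#' @return (invisibly) the descriptor path.
#' @export
writeSectionImage <- function(image, path) {
  stopifnot(is(image, "SectionImage"))
  pages <- lapply(image@channels, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  desc <- list(channels = as.list(channelNames(image)),
               pixel_size_um = pixelSize(image))
  descPath <- paste0(path, ".json")
  jsonlite::write_json(desc, descPath, auto_unbox = TRUE, digits = NA)
  invisible(descPath)
}

#' @rdname writeSectionImage
#' @param tissue optional logical tissue mask to attach on read.
#' @return `readSectionImage()`: a [SectionImage-class].
#' @export
readSectionImage <- function(path, tissue = NULL) {
  desc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  names(pages) <- desc$channels
  SectionImage(pages, pixelSize = desc$pixel_size_um, tissueMask = tissue)
}

#' Write ground truth as a JSON sidecar
#'
#' Serializes the scalar and tabular ground truth (types, areas, flags,
#' centroid tables, convex-hull fiber polygons and pixel size). The dense
#' label and mask rasters are not serialized; keep the in-memory object
#' when pixel-exact scoring is needed.
#'
#' @param truth a [SectionGroundTruth-class].
#' @param path JSON file path.
#' @return (invisibly) `path`.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "SectionGroundTruth"))
  out <- list(
    pixel_size_um = pixelSize(truth),
    fiber_types = fiberTypes(truth),
    fiber_areas_um2 = fiberAreas(truth),
    central_nucleus = truth@centralNucleus,
    punctum = truth@punctum,
    nuclei = truth@nuclei,
    puncta = truth@puncta,
    cells = truth@cells,
    polygons = lapply(fiberPolygons(truth), function(p)
      list(row = p[, 1L], col = p[, 2L]))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read a cohort table as CSV
#'
#' One row per animal with a documented column dictionary (see
#' [generateCohort()] for the columns).
#'
#' @param cohort data.frame from [generateCohort()].
#' @param path CSV file path.
#' @return `readCohort()`: the cohort data.frame.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
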