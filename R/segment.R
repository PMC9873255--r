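#' Segmented fibers of one section
#'
#' Result of [segmentFibers()]: a relabeled fiber label image plus a
#' per-fiber table. The table gains per-channel mean intensities, a type
#' label and a hybrid flag after [assignFiberTypes()].
#'
#' @slot labels integer matrix; 0 = background, k = fiber k.
#' @slot table data.frame with one row per fiber: `id`, `npixels`,
#'   `area_um2`, `touches_border`, and after typing `mean_<channel>`,
#'   `type`, `hybrid`.
#' @slot pixelSize um/px.
#'
#' @seealso [segmentFibers()], [assignFiberTypes()]
#' @export
setClass("FiberSet",
  representation(labels = "matrix", table = "data.frame",
                 pixelSize = "numeric")
)

setMethod("show", "FiberSet", function(object) {
  cat(sprintf("FiberSet: %d fibers at %.3g um/px\n", nrow(object@table),
              object@pixelSize))
  if ("type" %in% names(object@table)) {
    tt <- table(factor(object@table$type, levels = FIBER_TYPES))
    cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = " "),
        "\n")
  }
})

#' @rdname accessors
setMethod("fiberLabels", "FiberSet", function(x) x@labels)
#' @rdname accessors
setMethod("nFibers", "FiberSet", function(x) nrow(x@table))
#' @rdname accessors
setMethod("pixelSize", "FiberSet", function(x) x@pixelSize)
#' @rdname accessors
setMethod("fiberAreas", "FiberSet", function(x) x@table$area_um2)
#' @rdname accessors
setMethod("fiberTypes", "FiberSet", function(x) {
  if (!"type" %in% names(x@table))
    stop("fibers have not been typed yet; run assignFiberTypes()",
         call. = FALSE)
  x@table$type
})

#' Per-fiber table of a FiberSet
#'
#' @param x a [FiberSet-class].
#' @return the per-fiber data.frame.
#' @export
fiberTable <- function(x) {
  stopifnot(is(x, "FiberSet"))
  x@table
}

#' Segment muscle fibers from the laminin channel
#'
#' Binarizes the laminin channel with [huangThreshold()] and takes muscle
#' fibers as the connected components (4-connectivity) of the non-boundary
#' phase, mirroring the outline-then-select-particles approach of
#' interactive macros; the macro's manual add/delete step is replaced by
#' the programmatic area and border filters.
#'
#' @param image a [SectionImage-class] with a `laminin` channel.
#' @param minArea,maxArea particle area filter in um^2 (defaults 100 and
#'   `Inf`).
#' @param excludeBorder drop components touching the image border
#'   (default `TRUE`).
#' @return a [FiberSet-class]. Zero surviving components yield an empty
#'   set with a warning.
#' @examples
#' sec <- generateSection(sectionSpec(imageSize = 192, fiberCount = 15,
#'                                    seed = 4))
#' fs <- segmentFibers(sec$image)
#' nFibers(fs)
#' @export
segmentFibers <- function(image, minArea = 100, maxArea = Inf,
                          excludeBorder = TRUE) {
  stopifnot(is(image, "SectionImage"))
  lam <- getChannel(image, "laminin")
  bin <- .huangBinarize(lam)
  if (is.null(bin))
    stop("degenerate input: laminin channel occupies a single gray level",
         call. = FALSE)
  interior <- !bin$mask
  if (!is.null(tissueMask(image))) interior <- interior & tissueMask(image)
  lab <- as.matrix(EBImage::bwlabel(interior * 1))
  storage.mode(lab) <- "integer"
  k <- max(lab)
  if (k == 0L) {
    warning("no fiber regions survived thresholding", call. = FALSE)
    return(new("FiberSet", labels = lab,
               table = data.frame(id = integer(0), npixels = integer(0),
                                  area_um2 = numeric(0),
                                  touches_border = logical(0)),
               pixelSize = pixelSize(image)))
  }
  npix <- tabulate(lab[lab > 0L], nbins = k)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                     lab[, ncol(lab)]))
  touches <- seq_len(k) %in% border[border > 0L]
  area <- npix * pixelSize(image)^2
  keep <- area >= minArea & area <= maxArea
  if (excludeBorder) keep <- keep & !touches
  if (!any(keep)) {
    warning("no fiber regions survived the particle filters", call. = FALSE)
    lab[] <- 0L
    return(new("FiberSet", labels = lab,
               table = data.frame(id = integer(0), npixels = integer(0),
                                  area_um2 = numeric(0),
                                  touches_border = logical(0)),
               pixelSize = pixelSize(image)))
  }
  remap <- integer(k)
  remap[keep] <- seq_len(sum(keep))
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  lab2[nz] <- remap[lab[nz]]
  new("FiberSet", labels = lab2,
      table = data.frame(id = seq_len(sum(keep)),
                         npixels = npix[keep], area_um2 = area[keep],
                         touches_border = touches[keep]),
      pixelSize = pixelSize(image))
}

#' Match segmented fibers to ground-truth fibers
#'
#' Assigns each segmented fiber the ground-truth fiber with which it
#' shares the most pixels.
#'
#' @param fibers a [FiberSet-class].
#' @param truth a [SectionGroundTruth-class] from the same section.
#' @return data.frame with columns `id`, `truth_id`, `overlap` (pixel
#'   count), `area_um2` and `truth_area_um2`.
#' @export
matchFibers <- function(fibers, truth) {
  stopifnot(is(fibers, "FiberSet"), is(truth, "SectionGroundTruth"))
  seg <- fibers@labels
  tru <- truth@labels
  both <- seg > 0L & tru > 0L
  if (!any(both))
    return(data.frame(id = integer(0), truth_id = integer(0),
                      overlap = integer(0), area_um2 = numeric(0),
                      truth_area_um2 = numeric(0)))
  tab <- table(seg = seg[both], tru = tru[both])
  best <- apply(tab, 1L, which.max)
  ids <- as.integer(rownames(tab))
  truthIds <- as.integer(colnames(tab))[best]
  data.frame(id = ids, truth_id = truthIds,
             overlap = tab[cbind(seq_along(best), best)],
             area_um2 = fibers@table$area_um2[ids],
             truth_area_um2 = fiberAreas(truth)[truthIds])
}
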