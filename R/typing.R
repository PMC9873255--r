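#' Assign myosin-heavy-chain fiber types
#'
#' Scores each fiber on the three MHC channels (`mhc1`, `mhc2a`, `mhc2b`)
#' by its average signal inside the eroded fiber region (erosion avoids
#' boundary bleed from the laminin network). A channel is positive when
#' that average exceeds the channel's whole-image Huang threshold. Fibers
#' positive on exactly one channel get that type; fibers positive on none
#' are type 2x (the isoform unstained by all three antibodies); fibers
#' positive on several channels are assigned the channel with the largest
#' min-max-normalized signal and flagged as hybrid.
#'
#' @param fibers a [FiberSet-class].
#' @param image the [SectionImage-class] the fibers came from.
#' @param erodePx erosion margin in pixels before averaging (default 1).
#' @return the [FiberSet-class] with `type`, `hybrid` and `mean_<channel>`
#'   columns added to its table.
#' @export
assignFiberTypes <- function(fibers, image, erodePx = 1L) {
  stopifnot(is(fibers, "FiberSet"), is(image, "SectionImage"))
  mhcCh <- unname(MHC_ROLES)
  missing <- setdiff(mhcCh, channelNames(image))
  if (length(missing))
    stop("missing MHC channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  k <- nFibers(fibers)
  tab <- fibers@table
  if (k == 0L) {
    tab$type <- character(0)
    tab$hybrid <- logical(0)
    fibers@table <- tab
    return(fibers)
  }
  lab <- fibers@labels
  distIn <- .distanceIntoMask(lab > 0L)
  eroded <- lab > 0L & distIn > erodePx
  # fall back to the full region for fibers that erode away completely
  labE <- ifelse(eroded, lab, 0L)
  present <- tabulate(labE[labE > 0L], nbins = k) > 0L
  use <- labE
  if (!all(present)) {
    small <- lab %in% which(!present) & lab > 0L
    use[small] <- lab[small]
  }
  sel <- use > 0L
  f <- factor(use[sel], levels = seq_len(k))
  means <- sapply(channelNames(image), function(ch)
    as.numeric(tapply(getChannel(image, ch)[sel], f, mean)))
  colnames(means) <- channelNames(image)
  for (ch in channelNames(image)) tab[[paste0("mean_", ch)]] <- means[, ch]

  thr <- vapply(mhcCh, function(ch) {
    b <- .huangBinarize(getChannel(image, ch))
    if (is.null(b)) Inf else b$threshold   # flat channel: nothing positive
  }, numeric(1))
  pos <- sweep(means[, mhcCh, drop = FALSE], 2L, thr, `>`)
  norm <- vapply(mhcCh, function(ch) {
    rng <- range(getChannel(image, ch))
    if (diff(rng) == 0) rep(0, k) else (means[, ch] - rng[1L]) / diff(rng)
  }, numeric(k))
  norm <- matrix(norm, nrow = k, dimnames = list(NULL, mhcCh))

  typeOf <- names(MHC_ROLES)           # channel -> type label
  names(typeOf) <- unname(MHC_ROLES)
  npos <- rowSums(pos)
  type <- rep("2x", k)
  hybrid <- rep(FALSE, k)
  one <- npos == 1L
  if (any(one))
    type[one] <- typeOf[mhcCh[apply(pos[one, , drop = FALSE], 1L, which)]]
  multi <- npos > 1L
  if (any(multi)) {
    normPos <- norm
    normPos[!pos] <- -Inf
    # exact normalized ties (possible in synthetic imagery) fall back to
    # the larger raw mean
    for (i in which(multi)) {
      j <- order(-normPos[i, ], -means[i, mhcCh])[1L]
      type[i] <- typeOf[mhcCh[j]]
    }
    hybrid[multi] <- TRUE
  }
  tab$type <- type
  tab$hybrid <- hybrid
  fibers@table <- tab
  fibers
}

#' Per-type CSA means and histograms
#'
#' Arithmetic mean cross-sectional area per fiber type, plus fixed-width
#' CSA histograms starting at 0. Types absent from the section are
#' reported as missing (`NA` mean, no histogram), not as zero.
#'
#' @param fibers a typed [FiberSet-class] (see [assignFiberTypes()]).
#' @param binWidth histogram bin width in um^2 (default 200).
#' @return list with `means` (data.frame `type`, `n`, `mean_csa`) and
#'   `histograms` (per present type: list with `breaks`, `counts`).
#' @export
csaStatistics <- function(fibers, binWidth = 200) {
  types <- fiberTypes(fibers)
  if (length(types) == 0L)
    stop("at least one typed fiber is required", call. = FALSE)
  areas <- fiberAreas(fibers)
  means <- data.frame(
    type = FIBER_TYPES,
    n = vapply(FIBER_TYPES, function(t) sum(types == t), integer(1)),
    mean_csa = vapply(FIBER_TYPES, function(t) {
      a <- areas[types == t]
      if (length(a)) mean(a) else NA_real_
    }, numeric(1)),
    row.names = NULL)
  hists <- list()
  for (t in FIBER_TYPES) {
    a <- areas[types == t]
    if (!length(a)) next
    breaks <- seq(0, binWidth * ceiling(max(a) / binWidth + 1e-9),
                  by = binWidth)
    hists[[t]] <- list(breaks = breaks,
                       counts = hist(a, breaks = breaks, plot = FALSE)$counts)
  }
  list(means = means, histograms = hists)
}
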