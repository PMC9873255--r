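#' Positive-stain area fraction of a channel
#'
#' Thresholds the channel with [huangThreshold()] and reports the fraction
#' of tissue pixels that meet (exceed) the threshold — the quantification
#' used for Oil-Red-O fat and picrosirius-red fibrosis readouts. A channel
#' occupying a single gray level carries no stain signal and yields 0.
#'
#' @param image a [SectionImage-class].
#' @param role channel role to quantify (e.g. `"redstain"`).
#' @param tissue optional logical matrix overriding the image's tissue
#'   mask.
#' @return fraction in \[0, 1\].
#' @export
areaFraction <- function(image, role = "redstain", tissue = NULL) {
  stopifnot(is(image, "SectionImage"))
  ch <- getChannel(image, role)
  if (is.null(tissue)) tissue <- tissueMask(image)
  if (is.null(tissue))
    stop("no tissue mask available; supply 'tissue'", call. = FALSE)
  if (!any(tissue))
    stop("degenerate input: empty tissue mask", call. = FALSE)
  bin <- .huangBinarize(ch)
  if (is.null(bin)) return(0)
  sum(bin$mask & tissue) / sum(tissue)
}
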