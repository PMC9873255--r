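#' @name accessors
#' @title Accessors for tenomorph objects
#' @description Small accessor generics: `channelNames()` and
#'   `getChannel()` retrieve stain channels from a [SectionImage],
#'   `pixelSize()` the physical pixel size, `tissueMask()` the tissue
#'   mask; `fiberLabels()`, `fiberTypes()`, `fiberAreas()` and `nFibers()`
#'   query a [SectionGroundTruth].
#' @param x a tenomorph object.
#' @param role channel role name, e.g. `"laminin"`.
#' @return `channelNames()` a character vector; `getChannel()` a numeric
#'   matrix; `pixelSize()` a scalar (um/px); `tissueMask()` a logical
#'   matrix or `NULL`; `fiberLabels()` an integer label matrix;
#'   `fiberTypes()` a character vector; `fiberAreas()` a numeric vector
#'   (um^2); `nFibers()` an integer.
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, role) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setGeneric("fiberLabels", function(x) standardGeneric("fiberLabels"))
#' @rdname accessors
#' @export
setGeneric("fiberTypes", function(x) standardGeneric("fiberTypes"))
#' @rdname accessors
#' @export
setGeneric("fiberAreas", function(x) standardGeneric("fiberAreas"))
#' @rdname accessors
#' @export
setGeneric("nFibers", function(x) standardGeneric("nFibers"))

#' @rdname accessors
setMethod("channelNames", "SectionImage", function(x) names(x@channels))

#' @rdname accessors
setMethod("getChannel", "SectionImage", function(x, role) {
  if (!role %in% names(x@channels))
    stop("channel role '", role, "' not present (have: ",
         paste(names(x@channels), collapse = ", "), ")", call. = FALSE)
  x@channels[[role]]
})

#' @rdname accessors
setMethod("pixelSize", "SectionImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "SectionGroundTruth", function(x) x@pixelSize)
#' @rdname accessors
setMethod("tissueMask", "SectionImage", function(x) x@tissueMask)
#' @rdname accessors
setMethod("tissueMask", "SectionGroundTruth", function(x) x@tissueMask)
#' @rdname accessors
setMethod("fiberLabels", "SectionGroundTruth", function(x) x@labels)
#' @rdname accessors
setMethod("fiberTypes", "SectionGroundTruth", function(x) x@fiberTypes)
#' @rdname accessors
setMethod("fiberAreas", "SectionGroundTruth", function(x) x@fiberAreas)
#' @rdname accessors
setMethod("nFibers", "SectionGroundTruth",
          function(x) length(x@fiberTypes))

setMethod("dim", "SectionImage", function(x) dim(x@channels[[1L]]))

setMethod("show", "SectionImage", function(object) {
  d <- dim(object)
  cat(sprintf("SectionImage: %d x %d px at %.3g um/px\n", d[1], d[2],
              object@pixelSize))
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  cat("  tissueMask:",
      if (is.null(object@tissueMask)) "absent" else
        sprintf("%d px", sum(object@tissueMask)), "\n")
})

setMethod("show", "SectionGroundTruth", function(object) {
  k <- nFibers(object)
  cat(sprintf("SectionGroundTruth: %d fibers\n", k))
  tt <- table(factor(object@fiberTypes, levels = FIBER_TYPES))
  cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = " "), "\n")
  cat(sprintf("  central nuclei: %d fibers; puncta: %d fibers\n",
              sum(object@centralNucleus), sum(object@punctum)))
  cat(sprintf("  cells: %d interstitial, %d sublaminar\n",
              sum(object@cells$compartment == "interstitial"),
              sum(object@cells$compartment == "sublaminar")))
})

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:",
      length(object@sex) * length(object@genotype) *
        length(object@treatment) * length(object@timepoint),
      "cells x", object@nPerGroup, "animals\n")
  cat("  sex:", paste(object@sex, collapse = ","),
      " genotype:", paste(object@genotype, collapse = ","),
      " treatment:", paste(object@treatment, collapse = ","),
      " timepoint:", paste(object@timepoint, collapse = ","), "\n")
})

setMethod("show", "EffectModel", function(object) {
  cat("EffectModel:", nrow(object@effects), "(sex, timepoint) effect rows,",
      sprintf("noise CV %.3g, rho %.4g g/cm^3\n",
              object@noiseCv, object@density))
  cat("  AF:", paste(sprintf("%s=%.2f", names(object@af), object@af),
                     collapse = " "), "\n")
})

setMethod("show", "SectionSpec", function(object) {
  cat(sprintf("SectionSpec: %d fibers on %d^2 px at %.3g um/px (seed %d)\n",
              object@fiberCount, object@imageSize, object@pixelSize,
              object@seed))
})

setMethod("show", "MorphologyDelta", function(object) {
  cat(sprintf("MorphologyDelta: dFN=%.3f dFL=%.3f\n", object@fn, object@fl))
  cat("  dCSA:", paste(sprintf("%s=%.3f", names(object@csa), object@csa),
                       collapse = " "), "\n")
})

setMethod("show", "DecompositionResult", function(object) {
  cat(sprintf("DecompositionResult (%s): ratio %.4f, deficit %.4f\n",
              object@method, object@massRatio, object@deficit))
  if (object@degenerate) {
    cat("  shares undefined (ratio = 1)\n")
  } else {
    cat("  shares:",
        paste(sprintf("%s=%.1f%%", names(object@shares),
                      100 * object@shares), collapse = " "),
        if (object@remainder != 0)
          sprintf(" remainder=%.1f%%", 100 * object@remainder) else "",
        "\n")
  }
})

setMethod("show", "ValidationRegression", function(object) {
  cat(sprintf(
    "ValidationRegression: slope %.3f, intercept %.3f, r^2 %.3f, p %.3g (n=%d)\n",
    object@slope, object@intercept, object@rSquared, object@pValue,
    object@n))
})

setMethod("show", "StatResult", function(object) {
  cat("StatResult (", object@correction, " correction)\n", sep = "")
  print(object@effects, row.names = FALSE)
  if (nrow(object@pairwise))
    cat("  ", nrow(object@pairwise), "pairwise comparisons\n")
  cat(sprintf("  residual normality: W=%.3f, p=%.3g\n",
              object@normality$W, object@normality$p))
})

#' Extract the effect table or pairwise comparisons
#'
#' @param x a [StatResult].
#' @return `anovaEffects()` the data.frame of model terms; `pairwiseComparisons()`
#'   the data.frame of corrected pairwise contrasts.
#' @export
anovaEffects <- function(x) {
  stopifnot(is(x, "StatResult"))
  x@effects
}

#' @rdname anovaEffects
#' @export
pairwiseComparisons <- function(x) {
  stopifnot(is(x, "StatResult"))
  x@pairwise
}

#' Numeric summary of a decomposition or regression
#'
#' @param x a [DecompositionResult] or [ValidationRegression].
#' @return a named numeric vector of its fields.
#' @export
resultValues <- function(x) {
  if (is(x, "DecompositionResult")) {
    c(mass_ratio = x@massRatio, deficit = x@deficit,
      share_fl = unname(x@shares["fl"]), share_fn = unname(x@shares["fn"]),
      share_csa = unname(x@shares["csa"]), remainder = x@remainder)
  } else if (is(x, "ValidationRegression")) {
    c(slope = x@slope, intercept = x@intercept, r_squared = x@rSquared,
      p_value = x@pValue, n = x@n)
  } else stop("unsupported object")
}
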