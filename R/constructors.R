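#' Build a SectionImage
#'
#' @param channels named list of numeric matrices (stain role -> raster).
#' @param pixelSize physical pixel size in um/px.
#' @param tissueMask optional logical matrix of tissue pixels.
#' @return a [SectionImage-class] object.
#' @examples
#' img <- SectionImage(list(laminin = matrix(runif(64), 8, 8)), pixelSize = 1.5)
#' channelNames(img)
#' @export
SectionImage <- function(channels, pixelSize, tissueMask = NULL) {
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  if (!is.null(tissueMask)) {
    tissueMask <- matrix(as.logical(tissueMask), nrow(tissueMask),
                         ncol(tissueMask))
  }
  new("SectionImage", channels = channels, pixelSize = as.numeric(pixelSize),
      tissueMask = tissueMask)
}

#' Build a CohortDesign
#'
#' @param sex,genotype,treatment,timepoint factor levels to cross
#'   (subsets of M/F, WT/MKD/MCA, SHM/TEN, W1/W2/W8).
#' @param nPerGroup animals per design cell (the study used 5-7).
#' @param seed RNG seed.
#' @return a [CohortDesign-class] object.
#' @examples
#' cohortDesign(genotype = "WT", nPerGroup = 6, seed = 1)
#' @export
cohortDesign <- function(sex = c("M", "F"), genotype = c("WT", "MKD", "MCA"),
                         treatment = c("SHM", "TEN"),
                         timepoint = c("W1", "W2", "W8"),
                         nPerGroup = 6L, seed = 1L) {
  new("CohortDesign", sex = sex, genotype = genotype, treatment = treatment,
      timepoint = timepoint, nPerGroup = as.integer(nPerGroup),
      seed = as.integer(seed))
}

#' Build an EffectModel
#'
#' Most users will start from [defaultEffectModel()] and override fields;
#' this constructor validates a fully specified model.
#'
#' @param baseline data.frame of sex-specific sham baselines (see
#'   [EffectModel-class]).
#' @param effects data.frame of per-(sex, timepoint) multiplicative effect
#'   factors.
#' @param genotype data.frame of genotype scaling factors.
#' @param af named fiber-type area fractions (sum to 1).
#' @param noiseCv lognormal measurement-noise coefficient of variation.
#' @param density muscle density, g/cm^3.
#' @param architecture an [ArchitectureParams-class] object.
#' @param specificTension named numeric `c(SHM=, TEN=)`, N/cm^2.
#' @return an [EffectModel-class] object.
#' @export
effectModel <- function(baseline, effects, genotype, af, noiseCv = 0.05,
                        density = 1.056,
                        architecture = architectureParams(),
                        specificTension = c(SHM = 22, TEN = 14)) {
  new("EffectModel", baseline = baseline, effects = effects,
      genotype = genotype, af = af[FIBER_TYPES],
      noiseCv = as.numeric(noiseCv), density = as.numeric(density),
      architecture = architecture,
      specificTension = specificTension[c("SHM", "TEN")])
}

#' Load the packaged default effect model
#'
#' Reads the versioned configuration shipped in
#' `inst/extdata/effects-default.yaml`. The defaults are paper-inspired
#' generator choices that reproduce the qualitative structure of
#' tenotomy-induced atrophy — sex-specific mass loss, type-2b CSA loss
#' confined to males, larger fiber-number loss in females — not measured
#' values from any dataset.
#'
#' @param noiseCv override for the measurement-noise CV (default taken
#'   from the file).
#' @return an [EffectModel-class] object.
#' @examples
#' em <- defaultEffectModel()
#' em
#' @export
defaultEffectModel <- function(noiseCv = NULL) {
  path <- system.file("extdata", "effects-default.yaml",
                      package = "tenomorph", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  baseline <- do.call(rbind, lapply(cfg$baseline, as.data.frame))
  effects <- do.call(rbind, lapply(cfg$effects, as.data.frame))
  genotype <- do.call(rbind, lapply(cfg$genotype, as.data.frame))
  af <- unlist(cfg$area_fractions)
  arch <- architectureParams(flToMl = cfg$architecture$fl_to_ml,
                             pennationDeg = cfg$architecture$pennation_deg,
                             density = cfg$density)
  effectModel(baseline = baseline, effects = effects, genotype = genotype,
              af = af,
              noiseCv = if (is.null(noiseCv)) cfg$noise_cv else noiseCv,
              density = cfg$density, architecture = arch,
              specificTension = unlist(cfg$specific_tension))
}

#' Build a SectionSpec
#'
#' @param imageSize side length in pixels.
#' @param pixelSize um/px.
#' @param fiberCount number of fibers.
#' @param ribbonWidth laminin boundary ribbon width, px.
#' @param typeFractions named fiber-type fractions (sum to 1).
#' @param typeCsaMean,typeCsaSd named per-type CSA targets in um^2, used
#'   only to bias which tessellation cells receive which type.
#' @param centralNucleiRate,punctaRate per-fiber pathology probabilities.
#' @param fatFraction,fibrosisFraction red-stain target area fractions.
#' @param interstitialCellRate,sublaminarCellRate marker cells per fiber.
#' @param noiseSd additive Gaussian noise SD (intensities are in \[0,1\]).
#' @param blurSd Gaussian blur SD, px.
#' @param seed RNG seed.
#' @return a [SectionSpec-class] object.
#' @examples
#' sectionSpec(fiberCount = 50, imageSize = 256, seed = 7)
#' @export
sectionSpec <- function(imageSize = 512L, pixelSize = 1.5,
                        fiberCount = 200L, ribbonWidth = 3L,
                        typeFractions = c("1" = 0.02, "2a" = 0.26,
                                          "2x" = 0.33, "2b" = 0.39),
                        typeCsaMean = c("1" = 1400, "2a" = 1700,
                                        "2x" = 2100, "2b" = 2600),
                        typeCsaSd = c("1" = 400, "2a" = 450,
                                      "2x" = 500, "2b" = 550),
                        centralNucleiRate = 0, punctaRate = 0,
                        fatFraction = 0, fibrosisFraction = 0,
                        interstitialCellRate = 0, sublaminarCellRate = 0,
                        noiseSd = 0, blurSd = 0, seed = 1L) {
  new("SectionSpec", imageSize = as.integer(imageSize),
      pixelSize = as.numeric(pixelSize), fiberCount = as.integer(fiberCount),
      ribbonWidth = as.integer(ribbonWidth),
      typeFractions = typeFractions[FIBER_TYPES],
      typeCsaMean = typeCsaMean[FIBER_TYPES],
      typeCsaSd = typeCsaSd[FIBER_TYPES],
      centralNucleiRate = as.numeric(centralNucleiRate),
      punctaRate = as.numeric(punctaRate),
      fatFraction = as.numeric(fatFraction),
      fibrosisFraction = as.numeric(fibrosisFraction),
      interstitialCellRate = as.numeric(interstitialCellRate),
      sublaminarCellRate = as.numeric(sublaminarCellRate),
      noiseSd = as.numeric(noiseSd), blurSd = as.numeric(blurSd),
      seed = as.integer(seed))
}

#' Build ArchitectureParams
#'
#' @param flToMl fiber-length-to-muscle-length ratio (0, 1]. The default
#'   0.38 is a documented placeholder; substitute muscle-specific values
#'   when available.
#' @param pennationDeg pennation angle in degrees \[0, 90).
#' @param density muscle density, g/cm^3 (default 1.056).
#' @return an [ArchitectureParams-class] object.
#' @examples
#' architectureParams(flToMl = 0.4, pennationDeg = 5)
#' @export
architectureParams <- function(flToMl = 0.38, pennationDeg = 0,
                               density = 1.056) {
  new("ArchitectureParams", flToMl = as.numeric(flToMl),
      pennationDeg = as.numeric(pennationDeg), density = as.numeric(density))
}

#' Build a MorphologyDelta
#'
#' @param fn fiber-number tenotomy/sham ratio.
#' @param csa per-type CSA ratios; either a named numeric(4) over
#'   `"1","2a","2x","2b"` or a single value recycled to all types. Types
#'   absent from a section may be passed as `NA` and are treated as
#'   unchanged (ratio 1) with a warning.
#' @param af named fiber-type area fractions, summing to 1.
#' @param fl fiber-length ratio.
#' @param density muscle density, g/cm^3; cancels when the deltas are
#'   sham-normalized ratios and matters only in absolute-mass mode.
#' @return a [MorphologyDelta-class] object.
#' @examples
#' d <- morphologyDelta(fn = 0.9, csa = c("1"=1,"2a"=1,"2x"=1,"2b"=0.7),
#'                      af = c("1"=0,"2a"=0.25,"2x"=0.25,"2b"=0.5), fl = 0.8)
#' predictedMassRatio(d)
#' @export
morphologyDelta <- function(fn, csa, af, fl, density = 1.056) {
  if (length(csa) == 1L && is.null(names(csa)))
    csa <- setNames(rep(csa, 4L), FIBER_TYPES)
  csa <- csa[FIBER_TYPES]
  names(csa) <- FIBER_TYPES
  if (anyNA(csa)) {
    warning("CSA ratio missing for type(s) ",
            paste(FIBER_TYPES[is.na(csa)], collapse = ", "),
            "; treated as unchanged (ratio 1)", call. = FALSE)
    csa[is.na(csa)] <- 1
  }
  af <- af[FIBER_TYPES]
  names(af) <- FIBER_TYPES
  new("MorphologyDelta", fn = as.numeric(fn), csa = csa, af = af,
      fl = as.numeric(fl), density = as.numeric(density))
}
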