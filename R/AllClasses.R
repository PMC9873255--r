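#' @import methods
#' @importFrom stats aggregate as.formula coef complete.cases dnorm lm
#'   na.omit p.adjust pf pnorm quantile rbinom residuals rlnorm rnorm rpois
#'   runif sd setNames shapiro.test var
#' @importFrom graphics hist
#' @importFrom utils head read.csv write.csv
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

FIBER_TYPES <- c("1", "2a", "2x", "2b")
MHC_ROLES <- c("1" = "mhc1", "2a" = "mhc2a", "2b" = "mhc2b")

#' Multi-channel stained muscle section
#'
#' Container for a single muscle cross-section imaged in several stain
#' channels. Each channel is a numeric matrix of intensities in arbitrary
#' units (the synthetic generator uses the range \[0, 1\]); all channels
#' share one pixel grid. Channel names encode their stain role; the
#' conventional roles are `laminin`, `mhc1`, `mhc2a`, `mhc2b`, `dapi`,
#' `hematoxylin` and `redstain`, but additional marker channels (for
#' example `pdgfra`, `pax7`) are allowed. Stain chemistry (H&E, Oil Red O,
#' picrosirius red) is modeled as a single pre-extracted intensity channel
#' per stain.
#'
#' @slot channels named list of numeric matrices, one per stain channel,
#'   all with identical dimensions.
#' @slot pixelSize physical size of one pixel in micrometres per pixel.
#' @slot tissueMask optional logical matrix marking pixels that belong to
#'   the tissue cross-section, or `NULL` when unknown.
#'
#' @seealso [SectionImage()], [generateSection()], [segmentFibers()]
#' @export
setClass("SectionImage",
  representation(
    channels = "list",
    pixelSize = "numeric",
    tissueMask = "matrixOrNULL"
  )
)

setValidity("SectionImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("'channels' must contain at least one channel")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("'channels' must be a uniquely named list")
  if (!all(vapply(ch, function(m) is.matrix(m) && is.numeric(m), logical(1))))
    return("every channel must be a numeric matrix")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must share the same dimensions")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("'pixelSize' must be a single positive number (um/px)")
  if (!is.null(object@tissueMask)) {
    if (!identical(dim(object@tissueMask), dim(ch[[1L]])))
      return("'tissueMask' dimensions must match the channels")
  }
  TRUE
})

#' Ground truth for a synthetic muscle section
#'
#' Records everything the section generator knows before blur and noise are
#' applied: the fiber label image, per-fiber type labels and areas,
#' per-fiber pathology flags, the placed nuclei/puncta/cell centroids with
#' their compartments, and the true positive-stain mask for the red-stain
#' channel. Downstream morphometry is scored against this object.
#'
#' @slot labels integer matrix; 0 = background/boundary, k = fiber k.
#' @slot fiberTypes character vector, one of `"1"`, `"2a"`, `"2x"`, `"2b"`
#'   per fiber.
#' @slot fiberAreas numeric vector of true fiber areas in um^2.
#' @slot centralNucleus logical per-fiber flag: fiber contains a central
#'   (non-subsarcolemmal) nucleus.
#' @slot punctum logical per-fiber flag: fiber contains a basophilic
#'   punctum (hematoxylin-positive, DAPI-negative).
#' @slot nuclei data.frame of nucleus centroids (`row`, `col`, `fiber`,
#'   `central`); boundary nuclei have `fiber = 0`.
#' @slot puncta data.frame of punctum centroids (`row`, `col`, `fiber`).
#' @slot cells data.frame of marker-cell centroids (`marker`,
#'   `compartment`, `row`, `col`); compartments are `"interstitial"`
#'   (FAP-like) and `"sublaminar"` (satellite-cell-like).
#' @slot redMask logical matrix: true red-stain-positive pixels.
#' @slot tissueMask logical matrix of tissue pixels.
#' @slot pixelSize um/px, copied from the generating [SectionSpec].
#'
#' @seealso [generateSection()]
#' @export
setClass("SectionGroundTruth",
  representation(
    labels = "matrix",
    fiberTypes = "character",
    fiberAreas = "numeric",
    centralNucleus = "logical",
    punctum = "logical",
    nuclei = "data.frame",
    puncta = "data.frame",
    cells = "data.frame",
    redMask = "matrix",
    tissueMask = "matrix",
    pixelSize = "numeric"
  )
)

setValidity("SectionGroundTruth", function(object) {
  k <- max(0L, max(object@labels))
  if (length(object@fiberTypes) != k) return("one type label per fiber required")
  if (!all(object@fiberTypes %in% FIBER_TYPES))
    return("fiber types must be one of 1/2a/2x/2b")
  if (length(object@fiberAreas) != k || any(object@fiberAreas <= 0))
    return("fiber areas must be positive, one per fiber")
  if (length(object@centralNucleus) != k || length(object@punctum) != k)
    return("per-fiber flags must have one entry per fiber")
  TRUE
})

#' Cohort factorial design
#'
#' The full-factorial group structure of the tenotomy study: sex x genotype
#' x treatment x timepoint, with a common per-cell sample size. Genotypes
#' follow the study's labels: wild type (`WT`), muscle-specific IKKb
#' knockdown (`MKD`) and constitutively active IKKb (`MCA`). Treatments are
#' sham surgery (`SHM`) and tenotomy (`TEN`); timepoints are weeks 1, 2 and
#' 8 post-surgery.
#'
#' @slot sex,genotype,treatment,timepoint character vectors of factor
#'   levels to cross.
#' @slot nPerGroup animals per design cell.
#' @slot seed RNG seed for cohort generation.
#'
#' @seealso [cohortDesign()], [generateCohort()]
#' @export
setClass("CohortDesign",
  representation(
    sex = "character", genotype = "character", treatment = "character",
    timepoint = "character", nPerGroup = "integer", seed = "integer"
  )
)

setValidity("CohortDesign", function(object) {
  lv <- list(sex = c("M", "F"), genotype = c("WT", "MKD", "MCA"),
             treatment = c("SHM", "TEN"), timepoint = c("W1", "W2", "W8"))
  for (f in names(lv)) {
    x <- slot(object, f)
    if (length(x) == 0L) return(sprintf("factor '%s' has no levels", f))
    if (!all(x %in% lv[[f]]))
      return(sprintf("factor '%s' has levels outside {%s}", f,
                     paste(lv[[f]], collapse = ", ")))
  }
  if (object@nPerGroup < 1L) return("'nPerGroup' must be >= 1")
  TRUE
})

#' Multiplicative effect model for cohort generation
#'
#' Defines sex-specific sham baselines and the multiplicative morphology
#' effect factors applied to tenotomized animals, per (sex, timepoint)
#' cell. Tenotomized muscle mass is constructed through the cylinder
#' relation mass = FN x (sum_i AF_i CSA_i) x FL x rho, so the configured
#' factors are recoverable by the decomposition stage. Tabular noise is
#' multiplicative lognormal, parameterized by a coefficient of variation.
#'
#' @slot baseline data.frame, one row per sex, with columns `sex`,
#'   `body_mass_g`, `ta_mass_mg`, `fiber_number`, `csa_1`, `csa_2a`,
#'   `csa_2x`, `csa_2b` (um^2), `muscle_length_cm` and `is_scale` (IS mass
#'   relative to SS).
#' @slot effects data.frame, one row per (sex, timepoint), with columns
#'   `fn_ratio`, `fl_ratio`, `csa_ratio_1`, `csa_ratio_2a`, `csa_ratio_2x`,
#'   `csa_ratio_2b`; all in (0, 1.5].
#' @slot genotype data.frame with columns `genotype`, `csa_scale`
#'   (baseline CSA scaling, sham and tenotomy alike) and `ten_fl_scale`
#'   (extra fiber-length scaling in tenotomy only).
#' @slot af named numeric(4): fiber-type area fractions, summing to 1.
#' @slot noiseCv coefficient of variation of the lognormal measurement
#'   noise (0 = noise-free).
#' @slot density muscle density rho in g/cm^3.
#' @slot architecture [ArchitectureParams] of the simulated muscle.
#' @slot specificTension named numeric(2) `c(SHM=, TEN=)`: intrinsic force
#'   per unit PCSA (N/cm^2) used to synthesize peak tetanic force.
#'
#' @seealso [effectModel()], [defaultEffectModel()], [generateCohort()]
#' @export
setClass("EffectModel",
  representation(
    baseline = "data.frame", effects = "data.frame", genotype = "data.frame",
    af = "numeric", noiseCv = "numeric", density = "numeric",
    architecture = "ANY", specificTension = "numeric"
  )
)

setValidity("EffectModel", function(object) {
  need <- c("sex", "body_mass_g", "ta_mass_mg", "fiber_number", "csa_1",
            "csa_2a", "csa_2x", "csa_2b", "muscle_length_cm", "is_scale")
  if (!all(need %in% names(object@baseline)))
    return("baseline is missing required columns")
  rc <- c("fn_ratio", "fl_ratio", paste0("csa_ratio_", FIBER_TYPES))
  if (!all(c("sex", "timepoint", rc) %in% names(object@effects)))
    return("effects is missing required columns")
  rv <- unlist(object@effects[rc])
  if (any(rv <= 0) || any(rv > 1.5))
    return("effect ratios must lie in (0, 1.5]")
  if (length(object@af) != 4L || !setequal(names(object@af), FIBER_TYPES))
    return("'af' must be a named numeric(4) over fiber types 1/2a/2x/2b")
  if (any(object@af < 0) || abs(sum(object@af) - 1) > 1e-8)
    return("area fractions must be nonnegative and sum to 1")
  if (object@noiseCv < 0) return("'noiseCv' must be >= 0")
  if (object@density <= 0) return("'density' must be > 0")
  TRUE
})

#' Synthetic section specification
#'
#' Parameters for one synthetic stained section: geometry of the fiber
#' tessellation, fiber-type composition and size targets, pathology rates,
#' stain targets, and the blur/noise applied after ground truth is frozen.
#'
#' @slot imageSize image side length in pixels (square images).
#' @slot pixelSize um/px.
#' @slot fiberCount number of fibers to tessellate.
#' @slot ribbonWidth laminin boundary ribbon width in pixels.
#' @slot typeFractions named numeric(4): target fiber-type fractions,
#'   summing to 1.
#' @slot typeCsaMean,typeCsaSd named numeric(4): per-type CSA targets
#'   (um^2) used to bias the size-to-type assignment; the tessellation
#'   controls absolute sizes, these control which cells get which type.
#' @slot centralNucleiRate,punctaRate per-fiber probabilities in \[0, 1\].
#' @slot fatFraction,fibrosisFraction target red-stain area fractions of
#'   the tissue area (their sum must be <= 1).
#' @slot interstitialCellRate,sublaminarCellRate expected marker cells per
#'   fiber (FAP-like and satellite-cell-like).
#' @slot noiseSd additive Gaussian noise SD (intensity units).
#' @slot blurSd Gaussian blur SD in pixels.
#' @slot seed RNG seed.
#'
#' @seealso [sectionSpec()], [generateSection()]
#' @export
setClass("SectionSpec",
  representation(
    imageSize = "integer", pixelSize = "numeric", fiberCount = "integer",
    ribbonWidth = "integer", typeFractions = "numeric",
    typeCsaMean = "numeric", typeCsaSd = "numeric",
    centralNucleiRate = "numeric", punctaRate = "numeric",
    fatFraction = "numeric", fibrosisFraction = "numeric",
    interstitialCellRate = "numeric", sublaminarCellRate = "numeric",
    noiseSd = "numeric", blurSd = "numeric", seed = "integer"
  )
)

setValidity("SectionSpec", function(object) {
  if (object@imageSize < 32L) return("'imageSize' must be >= 32 px")
  if (object@pixelSize <= 0) return("'pixelSize' must be > 0")
  if (object@fiberCount < 1L) return("'fiberCount' must be >= 1")
  if (object@ribbonWidth < 1L) return("'ribbonWidth' must be >= 1 px")
  for (s in c("typeFractions", "typeCsaMean", "typeCsaSd")) {
    x <- slot(object, s)
    if (length(x) != 4L || !setequal(names(x), FIBER_TYPES))
      return(sprintf("'%s' must be named over fiber types 1/2a/2x/2b", s))
  }
  if (any(object@typeFractions < 0) ||
      abs(sum(object@typeFractions) - 1) > 1e-8)
    return("'typeFractions' must be nonnegative and sum to 1")
  for (s in c("centralNucleiRate", "punctaRate", "interstitialCellRate",
              "sublaminarCellRate")) {
    x <- slot(object, s)
    if (x < 0 || x > 1) return(sprintf("'%s' must lie in [0, 1]", s))
  }
  if (object@fatFraction < 0 || object@fibrosisFraction < 0 ||
      object@fatFraction + object@fibrosisFraction > 1)
    return("stain fractions must be >= 0 and sum to <= 1")
  if (object@noiseSd < 0 || object@blurSd < 0)
    return("'noiseSd' and 'blurSd' must be >= 0")
  TRUE
})

#' Muscle architecture parameters
#'
#' Fiber-length-to-muscle-length ratio, pennation angle and muscle density
#' for one muscle. The fiber-length/pennation prediction model this study
#' relied on is external prior work; here it is abstracted to these
#' configurable per-muscle constants (the shipped defaults are documented
#' placeholders, not measured mouse values).
#'
#' @slot flToMl dimensionless fiber-length-to-muscle-length ratio in (0, 1].
#' @slot pennationDeg pennation angle in degrees, in \[0, 90).
#' @slot density muscle density in g/cm^3 (default 1.056, the standard
#'   mammalian value).
#'
#' @seealso [architectureParams()], [computePCSA()]
#' @export
setClass("ArchitectureParams",
  representation(flToMl = "numeric", pennationDeg = "numeric",
                 density = "numeric")
)

setValidity("ArchitectureParams", function(object) {
  if (object@flToMl <= 0 || object@flToMl > 1)
    return("'flToMl' must lie in (0, 1]")
  if (object@pennationDeg < 0 || object@pennationDeg >= 90)
    return("'pennationDeg' must lie in [0, 90)")
  if (object@density <= 0) return("'density' must be > 0")
  TRUE
})

#' Morphological change ratios entering the cylinder mass model
#'
#' One set of tenotomy-to-sham morphology ratios: fiber number, per-type
#' fiber cross-sectional area, fiber length, the fixed fiber-type area
#' fractions, and muscle density. All ratios are dimensionless
#' tenotomy-over-sham-mean values (normalized within sex), under which the
#' density cancels from the predicted mass ratio; density is retained for
#' absolute-mass use of the cylinder model.
#'
#' @slot fn fiber-number ratio.
#' @slot csa named numeric(4): per-type CSA ratios.
#' @slot af named numeric(4): fiber-type area fractions (sum to 1); the
#'   model assumes these are unchanged by tenotomy.
#' @slot fl fiber-length ratio.
#' @slot density muscle density in g/cm^3.
#'
#' @seealso [morphologyDelta()], [predictedMassRatio()],
#'   [contributionShares()]
#' @export
setClass("MorphologyDelta",
  representation(fn = "numeric", csa = "numeric", af = "numeric",
                 fl = "numeric", density = "numeric")
)

setValidity("MorphologyDelta", function(object) {
  if (object@fn <= 0 || object@fl <= 0) return("ratios must be > 0")
  if (length(object@csa) != 4L || !setequal(names(object@csa), FIBER_TYPES))
    return("'csa' must be named over fiber types 1/2a/2x/2b")
  if (any(object@csa <= 0)) return("CSA ratios must be > 0")
  if (length(object@af) != 4L || !setequal(names(object@af), FIBER_TYPES))
    return("'af' must be named over fiber types 1/2a/2x/2b")
  if (any(object@af < 0) || abs(sum(object@af) - 1) > 1e-6)
    return("area fractions must be nonnegative and sum to 1")
  if (object@density <= 0) return("'density' must be > 0")
  TRUE
})

#' Result of the mass-deficit decomposition
#'
#' Predicted tenotomy-to-sham mass ratio and the partition of the predicted
#' deficit into fiber-length, fiber-number and fiber-CSA contributions.
#' With the `"log"` method the shares are exact (they sum to 1 whenever the
#' ratio differs from 1); with the `"one-at-a-time"` method an unallocated
#' interaction remainder is reported.
#'
#' @slot massRatio predicted tenotomy/sham mass ratio.
#' @slot deficit predicted mass deficit, 1 - ratio.
#' @slot shares named numeric(3) over `fl`, `fn`, `csa`: fraction of the
#'   deficit attributed to each morphological change.
#' @slot remainder unallocated interaction share (0 for the log method).
#' @slot method `"log"` or `"one-at-a-time"`.
#' @slot degenerate TRUE when the ratio equals 1 and shares are undefined.
#'
#' @seealso [contributionShares()]
#' @export
setClass("DecompositionResult",
  representation(massRatio = "numeric", deficit = "numeric",
                 shares = "numeric", remainder = "numeric",
                 method = "character", degenerate = "logical")
)

setValidity("DecompositionResult", function(object) {
  if (object@massRatio <= 0) return("'massRatio' must be > 0")
  if (!setequal(names(object@shares), c("fl", "fn", "csa")))
    return("'shares' must be named fl/fn/csa")
  if (object@method == "log" && !object@degenerate &&
      abs(sum(object@shares) - 1) > 1e-9)
    return("log-method shares must sum to 1")
  TRUE
})

#' Predicted-versus-measured validation regression
#'
#' Ordinary least squares of the measured mass deficit on the predicted
#' mass deficit across muscles, with the slope F-test p-value. A slope near
#' 1 with a significant correlation indicates the morphological
#' measurements account for the bulk of the mass loss.
#'
#' @slot slope,intercept OLS coefficients (measured on predicted).
#' @slot rSquared coefficient of determination in \[0, 1\].
#' @slot pValue p-value of the slope F-test.
#' @slot n number of paired observations (>= 3).
#'
#' @seealso [validatePredictions()]
#' @export
setClass("ValidationRegression",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", pValue = "numeric", n = "integer")
)

setValidity("ValidationRegression", function(object) {
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    return("'rSquared' must lie in [0, 1]")
  if (object@n < 3L) return("at least 3 paired observations required")
  if (object@pValue < 0 || object@pValue > 1)
    return("'pValue' must lie in [0, 1]")
  TRUE
})

#' Factorial ANOVA result with corrected pairwise comparisons
#'
#' Output of [nwayAnova()]: the factorial effect table (Type II sums of
#' squares), pairwise contrasts corrected by Sidak or FDR, and a
#' Shapiro-Wilk normality check of the model residuals.
#'
#' @slot effects data.frame of model terms with F statistics and p-values.
#' @slot pairwise data.frame of corrected pairwise comparisons (may have
#'   zero rows when pairwise testing is disabled).
#' @slot normality list with elements `W` and `p` from the Shapiro-Wilk
#'   test on residuals.
#' @slot correction `"sidak"` or `"fdr"`.
#'
#' @seealso [nwayAnova()]
#' @export
setClass("StatResult",
  representation(effects = "data.frame", pairwise = "data.frame",
                 normality = "list", correction = "character")
)

setValidity("StatResult", function(object) {
  p <- object@effects$p
  if (!is.null(p) && any(p < 0 | p > 1, na.rm = TRUE))
    return("effect p-values must lie in [0, 1]")
  if (!object@correction %in% c("sidak", "fdr", "none"))
    return("'correction' must be sidak, fdr or none")
  TRUE
})
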