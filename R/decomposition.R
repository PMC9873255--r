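#' Predicted tenotomy-to-sham mass ratio from the cylinder model
#'
#' Models fibers as cylinders: muscle mass is fiber number times the
#' area-fraction-weighted fiber cross-sectional area times fiber length
#' times density. For sham-normalized ratios the density cancels and the
#' predicted mass ratio is
#' `dFN x (sum_i AF_i dCSA_i) x dFL`; the predicted mass deficit is one
#' minus the ratio. The model assumes density and the fiber-type area
#' fractions are unchanged by tenotomy.
#'
#' @param delta a [MorphologyDelta-class].
#' @return the predicted mass ratio (dimensionless).
#' @examples
#' af <- c("1" = 0, "2a" = 0.25, "2x" = 0.25, "2b" = 0.5)
#' d <- morphologyDelta(fn = 0.9, csa = c("1"=1,"2a"=1,"2x"=1,"2b"=0.7),
#'                      af = af, fl = 0.8)
#' predictedMassRatio(d)  # 0.9 * (0.75 + 0.5*0.7... ) -- see vignette
#' @export
predictedMassRatio <- function(delta) {
  stopifnot(is(delta, "MorphologyDelta"))
  if (abs(sum(delta@af) - 1) > 1e-6)
    stop("area fractions must sum to 1", call. = FALSE)
  delta@fn * sum(delta@af * delta@csa) * delta@fl
}

#' Partition the predicted mass deficit into morphological contributions
#'
#' Splits the predicted deficit across the three multiplicative factors of
#' the cylinder model: fiber length, fiber number, and the area-weighted
#' CSA term. The default `"log"` method uses
#' `share_k = log(factor_k) / log(ratio)`, the unique exact additive
#' decomposition of a multiplicative model (shares sum to 1 whenever the
#' ratio differs from 1). The `"one-at-a-time"` method applies each factor
#' alone, `share_k = (1 - factor_k) / deficit`, and reports the
#' unallocated interaction remainder; `measuredDeficit` may replace the
#' predicted deficit in its denominator.
#'
#' @param delta a [MorphologyDelta-class].
#' @param method `"log"` (default) or `"one-at-a-time"`.
#' @param measuredDeficit optional measured deficit for the
#'   one-at-a-time denominator.
#' @return a [DecompositionResult-class]. A ratio of exactly 1 leaves the
#'   shares undefined and sets the degenerate flag.
#' @export
contributionShares <- function(delta, method = c("log", "one-at-a-time"),
                               measuredDeficit = NULL) {
  stopifnot(is(delta, "MorphologyDelta"))
  method <- match.arg(method)
  factors <- c(fl = delta@fl, fn = delta@fn,
               csa = sum(delta@af * delta@csa))
  ratio <- prod(factors)
  if (abs(ratio - 1) < 1e-12) {
    return(new("DecompositionResult", massRatio = ratio,
               deficit = 1 - ratio,
               shares = c(fl = NA_real_, fn = NA_real_, csa = NA_real_),
               remainder = NA_real_, method = method, degenerate = TRUE))
  }
  if (method == "log") {
    shares <- log(factors) / log(ratio)
    remainder <- 0
  } else {
    denom <- if (is.null(measuredDeficit)) 1 - ratio else measuredDeficit
    shares <- (1 - factors) / denom
    remainder <- 1 - sum(shares)
  }
  new("DecompositionResult", massRatio = ratio, deficit = 1 - ratio,
      shares = shares, remainder = remainder, method = method,
      degenerate = FALSE)
}

#' Tenotomy-to-sham morphology ratios for every tenotomized animal
#'
#' Normalizes each tenotomized animal's fiber number, per-type CSA, fiber
#' length and muscle mass to the mean of the sham animals in the same
#' normalization cell (by default the same sex, genotype and timepoint, in
#' line with normalizing to the sham average of the same sex).
#'
#' @param cohort data.frame from [generateCohort()] or with the same
#'   morphology columns.
#' @param af named fiber-type area fractions (default from
#'   [defaultEffectModel()]).
#' @param muscle `"ss"` or `"is"`: which muscle's mass defines the
#'   measured ratio.
#' @param by grouping columns defining the sham reference cell.
#' @return data.frame with one row per tenotomized animal: the group
#'   labels, `dfn`, `dcsa_1`..`dcsa_2b`, `dfl`, `measured_ratio`,
#'   `measured_deficit`, `predicted_ratio`, `predicted_deficit`.
#' @export
computeDeltas <- function(cohort, af = defaultEffectModel()@af,
                          muscle = c("ss", "is"),
                          by = c("sex", "genotype", "timepoint")) {
  muscle <- match.arg(muscle)
  massCol <- paste0(muscle, "_mass_mg")
  need <- c("treatment", by, massCol, "fiber_number", "fiber_length_cm",
            paste0("csa_", FIBER_TYPES))
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- interaction(cohort[by], drop = TRUE)
  ten <- cohort$treatment == "TEN"
  out <- vector("list", 0L)
  for (cell in levels(key)) {
    inCell <- key == cell
    sham <- cohort[inCell & !ten, , drop = FALSE]
    tenC <- cohort[inCell & ten, , drop = FALSE]
    if (nrow(tenC) == 0L) next
    if (nrow(sham) == 0L)
      stop("no sham animals for cell ", cell, call. = FALSE)
    shamMean <- function(col) mean(sham[[col]])
    d <- tenC[c(intersect("animal_id", names(tenC)), by)]
    d$dfn <- tenC$fiber_number / shamMean("fiber_number")
    for (t in FIBER_TYPES)
      d[[paste0("dcsa_", t)]] <-
        tenC[[paste0("csa_", t)]] / shamMean(paste0("csa_", t))
    d$dfl <- tenC$fiber_length_cm / shamMean("fiber_length_cm")
    d$measured_ratio <- tenC[[massCol]] / shamMean(massCol)
    d$measured_deficit <- 1 - d$measured_ratio
    d$predicted_ratio <- vapply(seq_len(nrow(d)), function(i) {
      predictedMassRatio(morphologyDelta(
        fn = d$dfn[i],
        csa = setNames(as.numeric(d[i, paste0("dcsa_", FIBER_TYPES)]),
                       FIBER_TYPES),
        af = af, fl = d$dfl[i]))
    }, numeric(1))
    d$predicted_deficit <- 1 - d$predicted_ratio
    out[[length(out) + 1L]] <- d
  }
  do.call(rbind, out)
}

#' Decompose a cohort's mass deficit into contribution shares
#'
#' Runs [computeDeltas()] and [contributionShares()] over a cohort.
#' `mode = "animal"` decomposes each tenotomized animal and averages the
#' shares within groups; `mode = "group"` first averages the morphology
#' ratios within groups and decomposes the group means. Both are provided
#' because a per-animal-then-average and a from-group-means reading of a
#' grouped decomposition are equally defensible.
#'
#' @inheritParams computeDeltas
#' @param method passed to [contributionShares()].
#' @param mode `"animal"` or `"group"`.
#' @return data.frame with one row per group cell: `by` columns, `n`,
#'   `mass_ratio`, `deficit`, `share_fl`, `share_fn`, `share_csa`,
#'   `remainder`.
#' @export
decomposeCohort <- function(cohort, af = defaultEffectModel()@af,
                            muscle = c("ss", "is"), method = "log",
                            mode = c("animal", "group"),
                            by = c("sex", "genotype", "timepoint")) {
  mode <- match.arg(mode)
  deltas <- computeDeltas(cohort, af = af, muscle = muscle, by = by)
  key <- interaction(deltas[by], drop = TRUE)
  rows <- lapply(levels(key), function(cell) {
    d <- deltas[key == cell, , drop = FALSE]
    mk <- function(i) morphologyDelta(
      fn = i$dfn,
      csa = setNames(as.numeric(i[paste0("dcsa_", FIBER_TYPES)]),
                     FIBER_TYPES),
      af = af, fl = i$dfl)
    if (mode == "group") {
      g <- as.data.frame(lapply(d[c("dfn", paste0("dcsa_", FIBER_TYPES),
                                    "dfl")], mean))
      res <- contributionShares(mk(g), method = method)
      v <- resultValues(res)
    } else {
      vs <- vapply(seq_len(nrow(d)), function(i)
        resultValues(contributionShares(mk(d[i, ]), method = method)),
        numeric(6))
      v <- rowMeans(vs)
    }
    cbind(d[1L, by, drop = FALSE],
          data.frame(n = nrow(d), mass_ratio = v[["mass_ratio"]],
                     deficit = v[["deficit"]], share_fl = v[["share_fl"]],
                     share_fn = v[["share_fn"]], share_csa = v[["share_csa"]],
                     remainder = v[["remainder"]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress the measured mass deficit on the predicted mass deficit
#'
#' Ordinary least squares validation of the cylinder model: a significant
#' correlation with slope near 1 indicates the morphological measurements
#' account for the bulk of the mass loss.
#'
#' @param predicted,measured paired deficit vectors (n >= 3).
#' @return a [ValidationRegression-class].
#' @export
validatePredictions <- function(predicted, measured) {
  ok <- is.finite(predicted) & is.finite(measured)
  predicted <- predicted[ok]; measured <- measured[ok]
  n <- length(predicted)
  if (n < 3L || length(measured) != n)
    stop("at least 3 paired observations are required", call. = FALSE)
  if (var(predicted) == 0)
    stop("degenerate input: zero variance in the predicted deficits",
         call. = FALSE)
  fit <- lm(measured ~ predicted)
  s <- summary(fit)
  new("ValidationRegression",
      slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
      rSquared = s$r.squared,
      pValue = unname(s$coefficients["predicted", "Pr(>|t|)"]),
      n = as.integer(n))
}
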