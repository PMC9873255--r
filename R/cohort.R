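# Evaluate expr under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Unit-mean multiplicative lognormal noise with coefficient of variation cv.
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic tenotomy cohort
#'
#' Produces one row per animal for the full factorial design. Sham animals
#' realize the sex-specific baselines; tenotomized animals realize the
#' baselines multiplied by their group's effect factors, each additionally
#' perturbed by unit-mean lognormal noise. Muscle mass is then constructed
#' through the cylinder relation
#' `mass = FN x (sum_i AF_i CSA_i) x FL x rho`, so the configured
#' morphological factors are exactly recoverable by the mass-deficit
#' decomposition when the noise CV is 0. Peak tetanic force is synthesized
#' as a treatment-dependent specific tension times the PCSA of the
#' realized muscle.
#'
#' @param design a [CohortDesign-class].
#' @param effects an [EffectModel-class]; see [defaultEffectModel()].
#' @return data.frame with one row per animal: group labels, body and
#'   muscle masses (SS/IS/TA), muscle length, fiber number, per-type CSA,
#'   predicted fiber length, peak tetanic force, plus the realized
#'   per-animal true factors (`true_*` columns) for recovery tests. Fiber
#'   number is an expected (continuous) count.
#' @examples
#' cohort <- generateCohort(cohortDesign(genotype = "WT", nPerGroup = 5,
#'                                       seed = 3),
#'                          defaultEffectModel(noiseCv = 0))
#' head(cohort[, c("sex", "treatment", "timepoint", "ss_mass_mg")])
#' @export
generateCohort <- function(design, effects) {
  validObject(design)
  validObject(effects)
  arch <- effects@architecture
  af <- effects@af
  rho <- effects@density
  cells <- expand.grid(sex = design@sex, genotype = design@genotype,
                       treatment = design@treatment,
                       timepoint = design@timepoint,
                       stringsAsFactors = FALSE)
  .withSeed(design@seed, {
    rows <- vector("list", nrow(cells) * design@nPerGroup)
    id <- 0L
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      bl <- effects@baseline[effects@baseline$sex == cell$sex, ]
      gt <- effects@genotype[effects@genotype$genotype == cell$genotype, ]
      if (nrow(bl) != 1L || nrow(gt) != 1L)
        stop("effect model lacks a baseline/genotype row for cell ",
             paste(unlist(cell), collapse = "/"), call. = FALSE)
      ef <- effects@effects[effects@effects$sex == cell$sex &
                              effects@effects$timepoint == cell$timepoint, ]
      if (nrow(ef) != 1L)
        stop("effect model lacks an effects row for ", cell$sex, "/",
             cell$timepoint, call. = FALSE)
      ten <- cell$treatment == "TEN"
      csa0 <- c(bl$csa_1, bl$csa_2a, bl$csa_2x, bl$csa_2b) * gt$csa_scale
      names(csa0) <- FIBER_TYPES
      # count fractions implied by the configured AREA fractions: the mean
      # fiber CSA then atrophies by exactly sum(af * csa_ratio), keeping the
      # generator and the ratio-form cylinder equation in exact agreement
      nf <- (af / csa0) / sum(af / csa0)
      fFn <- if (ten) ef$fn_ratio else 1
      fFl <- if (ten) ef$fl_ratio * gt$ten_fl_scale else 1
      fCsa <- if (ten) {
        setNames(c(ef$csa_ratio_1, ef$csa_ratio_2a, ef$csa_ratio_2x,
                   ef$csa_ratio_2b), FIBER_TYPES)
      } else setNames(rep(1, 4L), FIBER_TYPES)
      for (ai in seq_len(design@nPerGroup)) {
        id <- id + 1L
        cv <- effects@noiseCv
        rFn <- fFn * .lnoise(1L, cv)
        rFl <- fFl * .lnoise(1L, cv)
        rCsa <- fCsa * .lnoise(4L, cv)
        fn <- bl$fiber_number * rFn
        csa <- csa0 * rCsa
        lm0 <- bl$muscle_length_cm
        lmCm <- lm0 * rFl * .lnoise(1L, cv)
        lfCm <- lmCm * arch@flToMl
        # cylinder relation: g = count x cm^2 x cm x g/cm^3 (CSA um^2 -> cm^2)
        ssG <- fn * sum(nf * csa) * 1e-8 * lfCm * rho * .lnoise(1L, cv)
        isG <- ssG * bl$is_scale * .lnoise(1L, cv)
        pcsa <- ssG * cos(arch@pennationDeg * pi / 180) / (rho * lfCm)
        st <- effects@specificTension[[cell$treatment]]
        rows[[id]] <- data.frame(
          animal_id = sprintf("A%04d", id),
          sex = cell$sex, genotype = cell$genotype,
          treatment = cell$treatment, timepoint = cell$timepoint,
          body_mass_g = bl$body_mass_g * .lnoise(1L, cv),
          ss_mass_mg = ssG * 1000,
          is_mass_mg = isG * 1000,
          ta_mass_mg = bl$ta_mass_mg * .lnoise(1L, cv),
          muscle_length_cm = lmCm,
          fiber_number = fn,
          csa_1 = csa[["1"]], csa_2a = csa[["2a"]],
          csa_2x = csa[["2x"]], csa_2b = csa[["2b"]],
          fiber_length_cm = lfCm,
          p0_n = st * pcsa * .lnoise(1L, cv),
          true_fn_ratio = rFn, true_fl_ratio = rFl,
          true_csa_ratio_1 = rCsa[["1"]], true_csa_ratio_2a = rCsa[["2a"]],
          true_csa_ratio_2x = rCsa[["2x"]], true_csa_ratio_2b = rCsa[["2b"]],
          true_mass_ratio = rFn * sum(af * rCsa) * rFl,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}
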