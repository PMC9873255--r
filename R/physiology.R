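#' Predict fiber length from muscle length
#'
#' Applies the muscle's fiber-length-to-muscle-length ratio, abstracting
#' the architecture model this measurement chain relies on to a
#' configurable constant. The normalized fiber length that enters the mass
#' decomposition is this prediction divided by the sex-matched sham mean
#' (see [computeDeltas()]).
#'
#' @param muscleLength optimal muscle length in cm (positive; vectorized).
#' @param params an [ArchitectureParams-class].
#' @return fiber length in cm.
#' @export
predictFiberLength <- function(muscleLength, params = architectureParams()) {
  stopifnot(is(params, "ArchitectureParams"))
  if (any(!is.finite(muscleLength)) || any(muscleLength <= 0))
    stop("muscle length must be positive", call. = FALSE)
  muscleLength * params@flToMl
}

#' Physiological cross-sectional area
#'
#' `PCSA = m cos(theta) / (rho Lf)` with mass in g, fiber length in cm and
#' density in g/cm^3, giving cm^2 — the denominator that normalizes peak
#' tetanic force to specific tension.
#'
#' @param mass muscle mass in g (positive; vectorized).
#' @param fiberLength fiber length in cm (positive; vectorized).
#' @param params an [ArchitectureParams-class] supplying the pennation
#'   angle and density.
#' @return PCSA in cm^2.
#' @examples
#' computePCSA(0.1, 0.5, architectureParams(flToMl = 1, pennationDeg = 0,
#'                                          density = 1.056))
#' @export
computePCSA <- function(mass, fiberLength, params = architectureParams()) {
  stopifnot(is(params, "ArchitectureParams"))
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("mass must be positive", call. = FALSE)
  if (any(!is.finite(fiberLength)) || any(fiberLength <= 0))
    stop("fiber length must be positive", call. = FALSE)
  mass * cos(params@pennationDeg * pi / 180) /
    (params@density * fiberLength)
}

#' Specific tension
#'
#' Peak tetanic force normalized to PCSA (N/cm^2), a measure of intrinsic
#' contractile quality.
#'
#' @param p0 peak tetanic force in N (vectorized).
#' @param pcsa physiological cross-sectional area in cm^2 (positive).
#' @return specific tension in N/cm^2.
#' @export
specificTension <- function(p0, pcsa) {
  if (any(!is.finite(pcsa)) || any(pcsa <= 0))
    stop("PCSA must be positive", call. = FALSE)
  p0 / pcsa
}

#' Append physiology columns to a cohort table
#'
#' Computes predicted fiber length, PCSA and specific tension for every
#' animal from its SS mass, muscle length and peak tetanic force.
#'
#' @param cohort data.frame with `ss_mass_mg`, `muscle_length_cm` and
#'   `p0_n` columns.
#' @param params an [ArchitectureParams-class].
#' @return the cohort with `pred_fiber_length_cm`, `pcsa_cm2` and
#'   `specific_tension_n_cm2` columns added.
#' @export
appendPhysiology <- function(cohort, params = architectureParams()) {
  need <- c("ss_mass_mg", "muscle_length_cm", "p0_n")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lf <- predictFiberLength(cohort$muscle_length_cm, params)
  pcsa <- computePCSA(cohort$ss_mass_mg / 1000, lf, params)
  cohort$pred_fiber_length_cm <- lf
  cohort$pcsa_cm2 <- pcsa
  cohort$specific_tension_n_cm2 <- specificTension(cohort$p0_n, pcsa)
  cohort
}
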