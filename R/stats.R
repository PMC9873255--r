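#' Normalize values to a sham-group mean
#'
#' Divides each value by the mean of the matching sham group — the
#' normalization applied throughout the study ("to the average of the sham
#' group of the same sex"). The low-level form takes the sham values
#' directly; [shamNormalize()] applies it across a cohort table.
#'
#' @param values numeric vector to normalize.
#' @param sham numeric vector of sham-group values (nonempty, nonzero
#'   mean).
#' @return `values / mean(sham)`.
#' @examples
#' normalizeToSham(9, c(10, 12, 14))  # 0.75
#' @export
normalizeToSham <- function(values, sham) {
  if (length(sham) == 0L)
    stop("empty sham group", call. = FALSE)
  m <- mean(sham)
  if (!is.finite(m) || m == 0)
    stop("sham-group mean must be finite and nonzero", call. = FALSE)
  values / m
}

#' Sham-normalize a cohort column within groups
#'
#' @param cohort data.frame with a `treatment` column (`SHM`/`TEN`).
#' @param response column to normalize.
#' @param by grouping columns defining the sham reference cell (default
#'   sex and genotype and timepoint).
#' @return the cohort with a `<response>_norm` column added.
#' @export
shamNormalize <- function(cohort, response,
                          by = c("sex", "genotype", "timepoint")) {
  if (!response %in% names(cohort))
    stop("no column '", response, "'", call. = FALSE)
  key <- interaction(cohort[by], drop = TRUE)
  out <- rep(NA_real_, nrow(cohort))
  for (cell in levels(key)) {
    i <- key == cell
    sham <- cohort[[response]][i & cohort$treatment == "SHM"]
    out[i] <- normalizeToSham(cohort[[response]][i], sham)
  }
  cohort[[paste0(response, "_norm")]] <- out
  cohort
}

#' Per-animal ratio normalization
#'
#' Divides a mass by a within-animal reference mass — e.g. tenotomized
#' supraspinatus mass over the intact tibialis anterior of the same mouse,
#' or muscle mass over body mass.
#'
#' @param mass numeric vector.
#' @param reference positive numeric vector (recycled if scalar).
#' @return elementwise `mass / reference`.
#' @export
ratioNormalize <- function(mass, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference mass must be positive", call. = FALSE)
  mass / reference
}

#' Sidak multiple-testing adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons.
#'
#' @param p raw p-values.
#' @param m number of comparisons (default `length(p)`).
#' @return adjusted p-values, capped at 1.
#' @export
sidakAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, 1 - (1 - p)^m)
}

#' Factorial ANOVA with corrected pairwise comparisons
#'
#' Fits the full-factorial linear model (all interactions) for up to three
#' crossed factors, computes Type II sums of squares (appropriate for the
#' mildly unbalanced 5-7-per-cell designs of this kind of study), and
#' reports pairwise contrasts of `pairwiseFactor` within every combination
#' of the remaining factors — the "within the same sex and timepoint"
#' comparisons of the figure annotations — corrected by Sidak (the study's
#' two-way convention) or Benjamini-Hochberg FDR (its three-way
#' convention). Residual normality is checked with Shapiro-Wilk and
#' reported, never acted on.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param factors 1-3 factor column names.
#' @param correction `"sidak"` or `"fdr"`.
#' @param pairwise compute pairwise contrasts (disable for speed in
#'   simulations).
#' @param pairwiseFactor which factor to contrast (default the first).
#' @return a [StatResult-class].
#' @examples
#' cohort <- generateCohort(cohortDesign(genotype = "WT", nPerGroup = 5,
#'                                       seed = 11), defaultEffectModel())
#' res <- nwayAnova(cohort, "ss_mass_mg", c("treatment", "sex"), "sidak")
#' anovaEffects(res)
#' @export
nwayAnova <- function(data, response, factors,
                      correction = c("sidak", "fdr"), pairwise = TRUE,
                      pairwiseFactor = factors[1L]) {
  correction <- match.arg(correction)
  if (length(factors) < 1L || length(factors) > 3L)
    stop("between 1 and 3 factors are supported", call. = FALSE)
  miss <- setdiff(c(response, factors), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- data[c(response, factors)]
  drop <- !complete.cases(df)
  if (any(drop)) {
    message(sum(drop), " incomplete row(s) removed")
    df <- df[!drop, , drop = FALSE]
  }
  for (f in factors) df[[f]] <- factor(df[[f]])
  cells <- table(df[factors])
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    lab <- apply(empty, 1L, function(i)
      paste(mapply(function(f, j) dimnames(cells)[[f]][j],
                   seq_along(factors), i), collapse = "/"))
    stop("empty design cell(s) make the full-factorial model inestimable: ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  form <- as.formula(paste(response, "~", paste(factors, collapse = "*")))
  fit <- lm(form, data = df)
  if (fit$df.residual < 1L)
    stop("no residual degrees of freedom; more replication is needed",
         call. = FALSE)
  a2 <- car::Anova(fit, type = 2)
  eff <- data.frame(term = rownames(a2), df = a2$Df,
                    sumsq = a2[["Sum Sq"]], statistic = a2[["F value"]],
                    p = a2[["Pr(>F)"]], row.names = NULL)
  eff <- eff[eff$term != "Residuals", , drop = FALSE]

  pw <- data.frame()
  if (pairwise) {
    byF <- setdiff(factors, pairwiseFactor)
    em <- emmeans::emmeans(fit, specs = pairwiseFactor,
                           by = if (length(byF)) byF else NULL)
    adj <- if (correction == "sidak") "sidak" else "fdr"
    prs <- summary(emmeans::contrast(em, method = "pairwise", adjust = adj))
    raw <- summary(emmeans::contrast(em, method = "pairwise",
                                     adjust = "none"))
    pw <- as.data.frame(prs)
    class(pw) <- "data.frame"
    pw$p_raw <- as.data.frame(raw)$p.value
    names(pw)[names(pw) == "p.value"] <- "p_adj"
    pw$correction <- correction
  }
  res <- stats::residuals(fit)
  norm <- if (length(res) >= 3L && length(res) <= 5000L &&
              diff(range(res)) > 0) {
    sw <- shapiro.test(res)
    list(W = unname(sw$statistic), p = sw$p.value)
  } else list(W = NA_real_, p = NA_real_)
  new("StatResult", effects = eff, pairwise = pw, normality = norm,
      correction = correction)
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector with 3 <= n <= 5000 and nonzero spread.
#' @return list with `W` and `p`.
#' @export
shapiroWilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("sample size must lie in [3, 5000]", call. = FALSE)
  if (diff(range(values)) == 0)
    stop("degenerate input: all values identical", call. = FALSE)
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}
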