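# Independent brute-force oracle for the minimum-fuzziness threshold:
# evaluates the fuzziness definition directly at every candidate level.
naiveHuangThreshold <- function(counts, levels = seq_along(counts) - 1) {
  occ <- counts > 0
  g <- levels[occ]
  w <- counts[occ]
  C <- max(g) - min(g)
  shannon <- function(u) {
    if (u <= 0 || u >= 1) return(0)
    -u * log(u) - (1 - u) * log(1 - u)
  }
  best <- Inf
  bestT <- NA
  for (t in g[-length(g)]) {
    bg <- g <= t
    mu0 <- sum(w[bg] * g[bg]) / sum(w[bg])
    mu1 <- sum(w[!bg] * g[!bg]) / sum(w[!bg])
    E <- 0
    for (i in seq_along(g)) {
      mu <- if (bg[i]) mu0 else mu1
      u <- 1 / (1 + abs(g[i] - mu) / C)
      E <- E + w[i] * shannon(u)
    }
    if (E < best - 1e-15) {
      best <- E
      bestT <- t
    }
  }
  bestT
}

# Small hand-built section image: rectangular fibers on a bright boundary
# grid, for rule-level tests that need full control of intensities.
# 'fiberValues' is a list per fiber of named channel intensities.
toySection <- function(n = 40, fibers = list(c(r1 = 6, r2 = 16, c1 = 6, c2 = 16),
                                             c(r1 = 24, r2 = 34, c1 = 24, c2 = 34)),
                       fiberValues = NULL, pixelSize = 1,
                       channels = c("laminin", "mhc1", "mhc2a", "mhc2b",
                                    "dapi", "hematoxylin", "redstain")) {
  bg <- 0.05
  mk <- function() matrix(bg, n, n)
  ch <- sapply(channels, function(x) mk(), simplify = FALSE)
  lam <- mk()
  lam[] <- 0.85  # everything is boundary except the fiber interiors
  for (i in seq_along(fibers)) {
    f <- fibers[[i]]
    rows <- f["r1"]:f["r2"]
    cols <- f["c1"]:f["c2"]
    lam[rows, cols] <- bg
    if (!is.null(fiberValues) && length(fiberValues) >= i) {
      for (nm in names(fiberValues[[i]]))
        ch[[nm]][rows, cols] <- fiberValues[[i]][[nm]]
    }
  }
  ch$laminin <- lam
  SectionImage(ch, pixelSize = pixelSize,
               tissueMask = matrix(TRUE, n, n))
}

# Effect model with every effect factor set to 1 (no tenotomy effect).
nullEffectModel <- function(noiseCv = 0) {
  em <- defaultEffectModel(noiseCv = noiseCv)
  for (col in c("fn_ratio", "fl_ratio", "csa_ratio_1", "csa_ratio_2a",
                "csa_ratio_2x", "csa_ratio_2b"))
    em@effects[[col]] <- 1
  em@genotype$csa_scale <- 1
  em@genotype$ten_fl_scale <- 1
  em
}

# Effect model realizing one hand-set factor combination for all cells.
flatEffectModel <- function(fn = 1, fl = 1,
                            csa = c("1" = 1, "2a" = 1, "2x" = 1, "2b" = 1),
                            af = NULL, noiseCv = 0) {
  em <- nullEffectModel(noiseCv = noiseCv)
  em@effects$fn_ratio <- fn
  em@effects$fl_ratio <- fl
  for (t in names(csa)) em@effects[[paste0("csa_ratio_", t)]] <- csa[[t]]
  if (!is.null(af)) em@af <- af[c("1", "2a", "2x", "2b")]
  validObject(em)
  em
}
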