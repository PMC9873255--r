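#' Huang fuzzy-entropy automatic threshold
#'
#' Minimum-fuzziness threshold of Huang & Wang (1995), the "Huang" method
#' of common image-analysis software. For a candidate threshold t the
#' gray levels are split into background (g <= t) and foreground (g > t);
#' each level's membership to its class is `u = 1 / (1 + |g - mu_class| / C)`
#' with `C = g_max - g_min` the occupied gray-level range, and the
#' fuzziness is the Shannon fuzzy entropy
#' `-u log u - (1 - u) log(1 - u)` summed over all pixels. The returned
#' threshold minimizes this fuzziness; ties are broken toward the lowest
#' threshold. Pixels at or below the threshold are background.
#'
#' @param counts nonnegative histogram counts, one per gray level.
#' @param levels gray-level values matching `counts` (default
#'   `0:(length(counts)-1)`, the 8-bit convention).
#' @return the threshold as a gray-level value.
#' @examples
#' h <- rep(0, 256); h[11] <- 500; h[201] <- 500
#' huangThreshold(h)  # 10: the two-delta histogram has zero fuzziness
#' @export
huangThreshold <- function(counts, levels = seq_along(counts) - 1) {
  if (length(counts) != length(levels))
    stop("'counts' and 'levels' must have equal length", call. = FALSE)
  if (any(counts < 0)) stop("histogram counts must be >= 0", call. = FALSE)
  o <- order(levels)
  levels <- levels[o]; counts <- counts[o]
  occ <- counts > 0
  g <- levels[occ]; w <- counts[occ]
  if (length(g) < 2L)
    stop("degenerate input: histogram occupies fewer than 2 gray levels",
         call. = FALSE)
  C <- g[length(g)] - g[1L]
  W0 <- cumsum(w); S0 <- cumsum(w * g)
  Wt <- W0[length(w)]; St <- S0[length(w)]
  m <- length(g) - 1L   # candidate thresholds: every occupied level but the last
  fuzz <- numeric(m)
  for (i in seq_len(m)) {
    mu0 <- S0[i] / W0[i]
    mu1 <- (St - S0[i]) / (Wt - W0[i])
    mu <- c(rep(mu0, i), rep(mu1, length(g) - i))
    u <- 1 / (1 + abs(g - mu) / C)
    fuzz[i] <- sum(w * .shannonFuzzy(u))
  }
  g[which.min(fuzz)]
}

# Shannon fuzzy entropy term, with the u -> 0/1 limits taken as 0.
.shannonFuzzy <- function(u) {
  s <- numeric(length(u))
  ok <- u > 0 & u < 1
  uu <- u[ok]
  s[ok] <- -uu * log(uu) - (1 - uu) * log1p(-uu)
  s
}

# Histogram a continuous-intensity channel and threshold it by Huang's
# method. Returns list(mask, threshold) with mask = intensity > threshold,
# or NULL when the channel occupies a single gray level.
.huangBinarize <- function(m, nbins = 256L) {
  rng <- range(m)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(NULL)
  breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  idx <- pmin(pmax(findInterval(m, breaks, rightmost.closed = TRUE), 1L),
              nbins)
  counts <- tabulate(idx, nbins = nbins)
  if (sum(counts > 0) < 2L) return(NULL)
  t <- huangThreshold(counts, mids)
  # contrast guard: when the histogram is unimodal (e.g. a stain with no
  # positive structures, only noise), the minimum-fuzziness split falls
  # inside the noise and its two classes barely differ. Fall back to a
  # mid-range threshold so such channels score as signal-free.
  bgBins <- mids <= t
  mu0 <- sum(counts[bgBins] * mids[bgBins]) / sum(counts[bgBins])
  mu1 <- sum(counts[!bgBins] * mids[!bgBins]) / sum(counts[!bgBins])
  if (!is.finite(mu1 - mu0) || (mu1 - mu0) < 0.25 * diff(rng))
    t <- rng[1L] + 0.5 * diff(rng)
  list(mask = matrix(m > t, nrow(m), ncol(m)), threshold = t)
}
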