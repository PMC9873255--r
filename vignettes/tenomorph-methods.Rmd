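---
title: "Methods: fiber morphometry and the cylinder decomposition of muscle mass loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiber morphometry and the cylinder decomposition of muscle mass loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenomorph)
```

`tenomorph` quantifies tenotomy-induced muscle atrophy along its three
morphological routes — fiber thinning, fiber loss and fiber shortening —
and asks how much of the measured mass deficit each route explains. This
vignette is the package's account of the underlying models, the choices
made where the design was genuinely open, and the limits of what the
synthetic-data tests demonstrate.

## The cylinder model and its decomposition

A muscle is modeled as `FN` parallel cylindrical fibers of length `Lf`
and per-type cross-sectional areas `CSA_i`, with fiber-type area
fractions `AF_i` and tissue density `ρ`. Writing each quantity as a
dimensionless tenotomy-over-sham-mean ratio (normalized within sex), the
mass ratio is

$$\Delta m \;=\; \Delta FN \cdot \Big(\sum_i AF_i\,\Delta CSA_i\Big)
  \cdot \Delta FL,$$

with `ρ` canceling in ratio form (it is retained in the
`MorphologyDelta` type, default 1.056 g/cm³, for absolute-mass use). The
model assumes density and the area fractions are unchanged by tenotomy,
and omits pennation-angle change.

**AF means area fraction, and that choice matters.** If `AF_i` were
fiber *count* fractions, the weighted sum of per-type CSA *ratios* would
not equal the ratio of mean fiber CSAs whenever baseline CSAs differ by
type. Interpreting `AF_i` as the fraction of total fiber cross-sectional
*area* occupied by type *i* makes the identity exact: the mean CSA
atrophies by exactly `Σ AF_i ΔCSA_i`. The synthetic cohort generator
therefore derives per-type count fractions from the configured area
fractions (`n_i ∝ AF_i / CSA_i`), which is what makes the end-to-end
exactness test — predicted ratio ≡ measured ratio to 1e-12 on noise-free
cohorts — achievable at machine precision rather than approximately.

**Contribution shares.** The deficit `1 − Δm` is attributed to the three
multiplicative factors. The default is the log decomposition
`share_k = log f_k / log Δm`: it is the unique exact additive splitting
of a multiplicative model (shares sum to 1 whenever `Δm ≠ 1`), so it was
chosen as the primary method. The one-at-a-time variant
(`share_k = (1 − f_k)/deficit`) is provided for comparison; its shares
overcount because single-factor deficits overlap, and the signed
remainder is reported rather than hidden. A ratio of exactly 1 flags the
result degenerate instead of dividing by `log 1`.

Whether a grouped decomposition should average per-animal shares or
decompose group-mean ratios is not determined by the model; both are
implemented (`decomposeCohort(mode = "animal" | "group")`) and agree
exactly in the noise-free limit.

**Validation.** `validatePredictions()` regresses measured on predicted
deficits by OLS and reports slope, intercept, r² and the slope t-test
p-value. Measured deficits are `1 − mass/shamMean` per muscle;
supraspinatus and infraspinatus can be pooled across sexes and
timepoints, which is how the acceptance script runs it.

## The morphometry chain

**Huang threshold.** `huangThreshold()` implements the minimum-fuzziness
criterion: for a candidate threshold the two classes get means `μ0, μ1`;
each gray level's membership is `u = 1/(1 + |g − μ|/C)` with `C` the
occupied gray-level range; the Shannon fuzzy entropy
`−u log u − (1−u) log(1−u)` is summed over pixels and minimized. Ties
break toward the lowest threshold, pixels at or below the threshold are
background, and a single-level histogram is a degenerate input. The
implementation uses cumulative sums; the test suite checks it against a
brute-force oracle that evaluates the definition at every candidate
level.

When a *continuous* channel is binarized (256 bins over the occupied
range), one guard is added: if the two classes the criterion finds
differ by less than 25% of the range, the histogram is effectively
unimodal — a stain with no positive structures, only noise — and the
threshold falls back to mid-range so the channel scores as signal-free.
Without this, a channel whose true positives are absent (e.g. MHC-1 in a
section with no type-1 fibers) would be split inside its noise floor and
every fiber would score positive.

**Segmentation.** Fibers are the connected components of the
below-threshold phase of the laminin channel, 4-connected (8-connectivity
would leak diagonally through thin boundary ribbons). The interactive
macro's manual add/delete step is replaced by programmatic filters:
minimum area 100 µm² (below typical mouse fiber CSA), no maximum, and
border exclusion on by default. Areas are always reported in µm²
(`pixels × pixelSize²`); coordinates are pixel-center, row-major,
0-based.

**Typing.** Each fiber's mean signal is taken inside the fiber eroded by
1 px (avoiding boundary bleed), and compared to the channel's whole-image
Huang threshold. Exactly one positive channel assigns that type; none
assigns 2x; several assign the largest min–max-normalized signal and set
a hybrid flag (exact normalized ties, which arise in synthetic imagery,
fall back to the larger raw mean). CSA histograms use fixed 200 µm² bins
from 0; absent types are reported missing, not zero.

**Counting rules.** A nucleus is a blob positive in both DAPI and
hematoxylin; a basophilic punctum is hematoxylin-positive and
DAPI-negative. Both are assigned to fibers by blob centroid, and "central"
requires the centroid inside the fiber eroded by a 2 px margin — nuclei
straddling the boundary fail the erosion test by construction. Marker
cells are classified by centroid: interstitial = outside every fiber;
sublaminar = inside a fiber within the margin of its boundary; blobs deep
inside a fiber count in neither compartment. Margins and bin widths are
configurable; the defaults (2 px, 200 µm²) are package choices, stated
here because no standard fixes them.

## The synthetic-data generator

The generator exists so that every stage has a no-download test surface
with known truth. It emulates:

* the factorial design — sex × genotype (WT, IKKβ-knockdown,
  constitutively-active IKKβ) × treatment (sham, tenotomy) × timepoint
  (weeks 1, 2, 8), 5–7 animals per cell;
* sex-specific sham baselines (female masses and CSAs lower) and
  multiplicative effect factors per (sex, timepoint), applied only to
  tenotomized animals, with muscle mass constructed through the cylinder
  relation so the decomposition is recoverable;
* multiplicative lognormal measurement noise for tabular data (masses
  and lengths are positive and CV-parameterized; unit mean so effects are
  unbiased), additive Gaussian noise for images;
* stained sections built as Poisson-disk centroids + discrete Voronoi
  cells clipped to a disk tissue mask, shrunk by a 3 px laminin ribbon —
  convex, disjoint, count-exact fibers; per-type MHC brightness (2x dark
  everywhere); boundary and central nuclei; hematoxylin-only puncta;
  a red-stain channel painted to a target area fraction; interstitial and
  sublaminar marker cells. Blur and noise are applied after ground truth
  is frozen.

The default effect factors (`inst/extdata/effects-default.yaml`, version
1) are paper-inspired generator choices: fiber-length loss dominating in
both sexes, type-2b CSA loss confined to males (log CSA share ≈ 27% at
weeks 2 and 8), fiber-number loss larger in females (share ≈ 35%), and a
week-8 mass ratio of 0.55 (males) / 0.68 (females). They are calibrated
targets for the generator, not measurements, and they were fixed once in
the configuration file; users wanting realism should refit the baselines
and ratios to their own data.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: staining variability and bleed-through,
uneven illumination, fiber splitting/branching, non-convex or
tightly-packed fiber geometry, out-of-focus nuclei, necrotic fibers, and
any transcriptional or contractile dynamics. Recovery that is exact here
is an algorithmic correctness statement, not an accuracy claim for real
histology.

## Physiology

Fiber length is predicted as `Lf = Lm × flToMl`; the architecture model
this ratio comes from is external prior work, so it is abstracted to
configurable per-muscle constants. The shipped defaults
(`flToMl = 0.38`, pennation 0°, ρ = 1.056 g/cm³) are documented
placeholders. `PCSA = m cos θ/(ρ Lf)` (g, cm, g/cm³ → cm²), and specific
tension is `P₀/PCSA`. With the cylinder construction, PCSA of a
noise-free synthetic muscle equals fiber number × mean fiber CSA, which
the tests verify to 1e-9; specific tension is invariant to uniform
geometric scaling when force scales with PCSA.

## Statistics

`nwayAnova()` fits the full-factorial linear model for up to three
crossed factors and uses **Type II** sums of squares — the conventional
choice for mildly unbalanced cell counts (n = 5–7) when no standard is
stated. Pairwise contrasts are the corrected contrasts of the factorial
model conditioned on the remaining factors (the "within the same sex and
timepoint" comparisons), not separate t-tests; Sidak correction follows
the two-way convention and Benjamini–Hochberg FDR the three-way one.
Empty design cells raise an error naming the cells. Residual normality is
tested by Shapiro–Wilk and reported only — no automatic switch to
nonparametric tests, since no fallback rule is stated for this workflow.
Incomplete rows are dropped cell-wise with a message.

## Problem sizes and tolerances used by the test suite

These are the package's own verification choices: noise-free cohort
exactness at 1e-12 (machine-precision identity of generator and model);
Huang oracle equivalence on 100 random histograms of 8–256 bins;
segmentation/typing recovery on 20 sections of 110 fibers at 448² px
(counts exact, areas within 5%, typing 100% clean and ≥ 95% under
additive noise with SD 10% of the intensity range); pathology and cell
counts exact on noise-free sections; decomposition recovery within
5 percentage points of the configured shares over 50 noisy cohorts
(CV 5%, n = 7), evaluated at weeks 2 and 8 — at week 1 the deficit is a
few percent, so the log-share denominator is near zero and share
estimation is ill-conditioned regardless of method; regression
unbiasedness over 1000 replicates; ANOVA type-I error within the binomial
95% band of 0.05 over 1000 null simulations.

## Known limitations

* Whole sections are quantified; the four-fields-at-20× sampling scheme
  of bench practice is not modeled (resolution enters only through the
  pixel size).
* Necrotic-fiber identification (a blinded-rater judgment with no stated
  criterion) is not implemented.
* H&E, Oil-Red-O and Sirius-Red inputs are modeled as single
  pre-extracted intensity channels; no RGB stain deconvolution.
* The fat and fibrosis targets are painted into one red-stain channel per
  synthetic section; the ground truth records their union.
* No mixed-effects modeling, and no per-fiber decomposition of the mass
  deficit (the model operates on group-level ratios).
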