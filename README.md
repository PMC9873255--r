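# tenomorph

Muscle fiber morphometry and mass-deficit decomposition for
tenotomy-induced atrophy.

Chronic tendon transection (tenotomy) — the rodent model of a chronic
rotator cuff tear — causes the released muscle to lose mass through three
morphological routes: fibers get thinner (reduced cross-sectional area,
CSA), fibers are lost outright (hypoplasia), and fibers shorten through
serial sarcomere subtraction. `tenomorph` is an R package for muscle
physiologists and histologists who want to quantify those routes from
stained cross-sections and per-animal measurement tables, and to ask how
much of the measured mass loss each route explains.

## What it computes

**Morphometry.** Sections stained for laminin, the myosin heavy chain
(MHC) isoforms, DAPI, hematoxylin, and fat/fibrosis stains are quantified
with the classic semi-automated recipe, made fully programmatic:
automatic thresholding by the Huang minimum-fuzziness criterion, fiber
segmentation as connected components of the non-boundary phase of the
laminin channel, per-fiber MHC typing by average signal (type 2x = dark
in all three MHC channels), per-type CSA statistics, positive-pixel area
fractions, central-nuclei and basophilic-puncta percentages, and
interstitial (FAP-like) versus sublaminar (satellite-cell-like) cell
densities.

**Decomposition.** Modeling fibers as cylinders, the tenotomy-to-sham
muscle mass ratio is

    Δm = ΔFN · (ΔCSA₁·AF₁ + ΔCSA₂ₐ·AF₂ₐ + ΔCSA₂ₓ·AF₂ₓ + ΔCSA₂ᵦ·AF₂ᵦ) · ΔFL · ρ

where ΔFN, ΔCSA_i and ΔFL are fiber-number, per-type CSA and fiber-length
ratios (tenotomy over the sex-matched sham mean), AF_i are the fiber-type
area fractions (assumed unchanged by tenotomy), and the density ρ cancels
in ratio form. The predicted deficit 1 − Δm is partitioned into fiber
length / number / CSA contribution shares — by exact log decomposition
(`share_k = log f_k / log Δm`, shares sum to 1) or one-factor-at-a-time —
and validated by regressing measured deficits on predicted ones.

**Physiology.** Fiber length predicted from muscle length, physiological
cross-sectional area `PCSA = m·cos θ / (ρ·Lf)`, and specific tension
`P₀ / PCSA`.

**Statistics & reporting.** Sham and body-mass/TA normalizations,
factorial ANOVA (Type II) with Sidak- or FDR-corrected pairwise
comparisons, Shapiro–Wilk normality checks, and figure-style summary
reports.

**Synthetic data.** A first-class generator produces cohort tables built
through the same cylinder relation (so the decomposition is exactly
recoverable) and stained-section images from a Poisson-disk/Voronoi
tessellation with complete ground truth — every stage of the pipeline is
testable without any download.

## Worked example

```r
library(tenomorph)

em <- defaultEffectModel()                       # paper-inspired defaults
co <- generateCohort(cohortDesign(genotype = "WT", nPerGroup = 6, seed = 1), em)

dec <- decomposeCohort(co, af = em@af, by = c("sex", "timepoint"))
subset(dec, timepoint == "W8")
#>   sex timepoint n mass_ratio deficit share_fl share_fn share_csa remainder
#> 5   F        W8 6      0.656   0.344    0.754    0.264   -0.0179         0
#> 6   M        W8 6      0.543   0.457    0.581    0.197    0.2227         0
```

Eight weeks after tenotomy this simulated wild-type cohort has lost 46%
(males) and 34% (females) of supraspinatus mass relative to sham. Fiber
shortening dominates in both sexes; CSA loss contributes ~22% of the male
deficit but essentially nothing in females, whose loss runs through fiber
number instead — the sex-specific pattern the generator emulates.

```r
deltas <- computeDeltas(subset(co, timepoint != "W1"), af = em@af)
validatePredictions(deltas$predicted_deficit, deltas$measured_deficit)
#> ValidationRegression: slope 0.958, intercept 0.011, r^2 0.866, p 4.6e-11 (n=24)
```

A slope near 1 says the three morphological measurements account for the
bulk of the measured mass loss.

```r
sec <- generateSection(sectionSpec(fiberCount = 150, seed = 1))
met <- sectionMetrics(sec$image)
met$fiber_number
#> [1] 150
met$csa$means
#>   type  n mean_csa
#> 1    1  1    767.2
#> 2   2a 43   1767.0
#> 3   2x 56   2152.4
#> 4   2b 50   2629.3
```

All 150 ground-truth fibers are recovered, with per-type mean CSA in
µm².

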