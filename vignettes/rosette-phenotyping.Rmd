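---
title: "Rosette shape phenotyping: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rosette shape phenotyping: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenorosette quantifies the shape of *Arabidopsis* rosettes from top-down
photographs and tests whether shape differs between genotypes and over
time. This vignette records the scientific model behind each stage, the
numerical conventions the implementation commits to, and the design
choices that were genuinely open — the things a maintainer would need to
know before changing a default.

## 1. Segmentation

A rosette photograph is separated into plant and background by
nearest-neighbour colour classification: the user supplies small sets of
foreground (leaf) and background (compost, tray) RGB exemplars, and each
pixel takes the label of its nearest exemplar in Euclidean RGB distance.
Distances are computed on raw 0–255 intensities with no colour-space
conversion, because exemplars are most naturally picked off the raw
image. Ties are resolved to background: a false negative at this stage is
recovered by dilation, while a false positive survives into the
descriptors.

Classification is followed by a morphological opening (erosion then
dilation with a disc structuring element, default radius 1 px each) that
removes isolated misclassified specks and restores ploughed-off border
pixels, and finally by a pot-region filter that deletes any foreground
outside the rectangle assigned to the pot — neighbouring plants leaking
into the frame are the dominant gross error in tray images. The
full-pipeline test plants a known rosette in a noisy synthetic scene and
requires pixelwise Jaccard ≥ 0.95 against the planted mask.

Physical calibration divides pixel measurements by a `px_per_mm` scale
factor obtained from an internal length reference (a 731 px reference of
100 mm gives 7.31 px/mm, a typical value for tray-level imaging at
3000×4000 px).

## 2. The twenty descriptors

All descriptors are computed on the largest 8-connected foreground
component (one plant per pot region); background is 4-connected, the
standard duality that makes hole detection consistent. The rosette is
treated as the union of unit-square pixels. Three conventions follow
from this and are used consistently:

* **Areas** are pixel counts (÷ scale²).
* **Convex-hull quantities** — hull perimeter and area, maximum
  diameter, minimal enclosing circle, minimal-area rotated rectangle —
  are computed on pixel *corners*. The hull then provably contains the
  pixel union, so `conhullarea ≥ area` and `compactness = area /
  conhullarea ≤ 1` hold exactly, and a digitised square of side 100
  yields hull area 10000 and hull perimeter 400 with no half-pixel bias.
* **Boundary lengths** (`circumference`, outer only; `bdrycount`, outer
  plus holes) use the 8-connected Moore-traced pixel-centre contour,
  simplified by Douglas–Peucker with a 1 px tolerance, plus a
  half-pixel offset correction of +π (the contour runs through pixel
  centres, half a pixel inside the true region edge). Raw Freeman chain
  length (1 axial, √2 diagonal) was rejected: it overestimates smooth
  boundaries by ≈ 5 % (measured 329.7 px against 2π·50 = 314.2 for a
  disc of radius 50), which would push disc roundness 10 % above 4π.
  The simplified-polygon estimator is exact on axis-aligned edges and
  within 0.6 % on digitised circles, satisfying both the "square
  roundness = 16" and the "disc perimeter within 3 %" anchors at once.

Principal-axis statistics are pixel-centre sums: with the centroid at
the origin and major/minor directions from the eigenvectors of the 2×2
second-central-moment matrix, `normsmallpax` is the mean absolute
coordinate along the **major** direction (the distance from the smaller
axis), `normlargepax` the mean absolute coordinate along the minor
direction, and `paxratio = excentricity = normlargepax / normsmallpax ≤
1`. The naming is counter-intuitive but matches the published
definitions, which name each statistic after the axis distances are
measured *from*; an `excentricity_mode = "moment"` switch substitutes
the moment-based eccentricity `sqrt(1 − λ_min/λ_max)` for users who want
the conventional quantity. `normrotmo` is the moment of inertia
normalised to a dimensionless ratio, `Σ r² / n²` (for a disc,
1/(2π) ≈ 0.159). These three are reported in pixel-ratio units and are
therefore invariant under recalibration, consistent with their "ratio"
unit in the descriptor table.

Degenerate masks do not crash: a single pixel or a collinear pixel row
yields the size-type descriptors and `NA` for the axis-ratio ones, and
downstream analyses drop `NA` rows per descriptor.

Unit behaviour is tested exhaustively: doubling the scale factor halves
every length, quarters every area, doubles `bdrytoarearatio` (mm⁻¹) and
leaves every ratio identical to 1e-9.

## 3. Growth rate

The relative rosette area growth rate between consecutive imaging dates
is the classical difference of logs, `RRAGR = (ln A₂ − ln A₁)/(t₂ −
t₁)`, attached at the interval midpoint. (The source text's equation
image was not recoverable; the difference-of-logs form is the standard
reading of "relative growth rate" reported at mean time, and makes
exponential growth return its rate exactly on every interval.) The
synthetic time-course generator scales *linear* leaf dimensions by
`exp(k Δt / 2)` so that area — the quantity the rate is defined on —
grows at exactly `k`; the round-trip test (mask → descriptors → RRAGR)
recovers `k` within 10 % on every interval, limited only by
rasterisation.

## 4. The statistics pipeline

**Transform policy.** Eleven size-like descriptors (the "Area group"
plus `bdryround`) are analysed on natural-log scale; shape ratios are
left untransformed. The policy is fixed rather than data-driven so runs
are reproducible; `shapiro_screen()` is provided as the advisory
normality check.

**Outlier screen.** Per descriptor, the mixed model is fitted once and
observations with Bonferroni-significant externally studentized
residuals (`p·n < α`, two-sided t with `n − k − 1` df) are removed in a
single pass — no iteration, matching "identify and remove". Calibration:
over 1,000 clean simulations the family-wise false-flag rate stays
below 0.05 (Bonferroni is conservative).

**Mixed model.** For each descriptor,

> value ~ ecotype + das (+ das²) + ecotype:das, random intercept per
> plant, AR(1) errors within plant,

fitted by REML with `nlme::lme`. The quadratic time term is included
exactly for the Area group, whose time courses rise monotonically with
visible curvature. The AR(1) index is the imaging *occasion* (rank of
DAS), not the calendar day: `corAR1` requires integer spacing, and with
five dates 3–5 days apart the distinction is minor compared with the
choice of AR(1) itself, which the source describes only as "structure …
specified to capture autocorrelation". Effect-level P-values for
ecotype, time (das and das² jointly) and interaction are Wald F tests of
the coefficient blocks with denominator df from the fit's
between/within-plant decomposition; under the null generative model the
ecotype test's type-I error at α = 0.05 lands in [0.03, 0.07]
(800-replicate check at a reduced 4×4 design), and 95 % Wald intervals
cover planted ecotype offsets and the time slope at ≈ 95 % on the full
19 × 12 × 5 design (40 replicates × 19 parameters).

**Pairwise contrasts.** "Post-hoc Tukey adjusted by Bonferroni" is
internally contradictory (two different corrections); the explicitly
stated adjustment wins: all C(L,2) pairwise contrasts of estimated
marginal means (ecotypes at the average of the observed dates, or dates
averaged over ecotypes) are tested with two-sided t statistics and
Bonferroni-multiplied P-values, then tiered `ns` / `<0.05` / `<0.01`.
With 19 ecotypes that is 171 contrasts.

**PCA.** Per time point, on descriptors centred and scaled to unit
variance; percent variance always sums to 100 and is invariant to
affine rescaling of any column. A `subset` option restricts the
analysis to the seven descriptors comparable with the earlier
Pérez-Pérez in-vitro study; since the published correspondence table is
not redistributable, the mapping (area, circumference, compactness,
maxdiam, plus hull/enclosing-circle stand-ins for the fitted-ellipse
metrics) is this package's own and is labelled as such.

**ReliefF.** Multi-class ReliefF with `diff = |a − b| / range`,
Manhattan nearest-neighbour search, k = 10 by default, every instance
used once in index order (deterministic; distance ties broken by
index), and miss contributions weighted by `P(C)/(1 − P(class))`. The
classification variant is implemented; the source mentions "regression"
once but ranks discrete ecotype classes, which is what the
classification variant does.

## 5. What the synthetic generator does and does not emulate

`simulate_descriptor_table()` is the generative twin of the mixed model:
fixed ecotype/time/interaction effects, a plant random intercept, and
stationary AR(1) errors over occasions, simulated in standardized units
and mapped onto each descriptor through a realistic baseline and scale
(e.g. area ≈ 500 mm² mid-experiment with ±0.2 log-unit ecotype spread;
RRAGR ≈ 0.12 day⁻¹; compactness ≈ 0.8 declining slowly). Log-flagged
columns are exponentiated so the table arrives on the raw scale, like
one extracted from images. Defaults follow the study design: 19
ecotypes × 12 replicates × 5 dates = 1,140 rows, ecotype offsets evenly
spaced over ±0.8 SD, interaction slopes over ±0.02 SD/day, between-plant
SD equal to the residual SD, ρ = 0.6.

Two honest limitations. First, descriptors are simulated independently,
whereas real shape descriptors are strongly cross-correlated; a green
PCA test on synthetic data therefore establishes that the machinery is
correct, *not* that it reproduces the published variance concentration
(that check is wired to run whenever a copy of the study's raw table is
placed at `inst/extdata/study_raw_descriptors.csv`). Second, rendered rosettes
are unions of elliptical blades and thin petiole bars (30 % of blade
width — wide enough to survive a radius-1 opening, thin enough that
long-petioled phenotypes show the low-compactness contrast); they span
the realistic compactness range but have none of the leaf overlap
texture of real plants, so segmentation tests certify the pipeline, not
field robustness.

## 6. Numerical choices and degenerate inputs

* Douglas–Peucker tolerance 1 px: below it, chain jaggedness survives;
  above ~1.5 px, square corners are cut. Not user-exposed.
* Welzl's minimal enclosing circle runs on hull vertices with a
  deterministic pseudo-shuffle (no global RNG side effects); containment
  tolerance 1e-7 px.
* Minimal-area rectangle: rotating calipers over hull edges (the
  optimum is edge-aligned for the hull of a finite point set; verified
  against a 0.1° orientation sweep).
* Collinear masks: moment-matrix eigenvalue ratio below 1e-9 flags the
  minor-axis statistics as `NA`.
* `fit_lme` with a single time point drops the time terms and the
  correlation structure and reduces to a one-way random-intercept
  layout whose fixed estimates equal the group means.
* All generators accept a seed, restore the caller's RNG state, and are
  bit-reproducible; test simulation sizes are scaled down from nominal
  counts (noted inline in the tests) to fit a single-CPU budget.

## 7. Worked example

```{r, eval = FALSE}
library(phenorosette)

## simulate the study design, analyse one descriptor end to end
tab <- simulate_descriptor_table(table_effect_spec(seed = 1))
tab <- apply_transforms(tab)
tab <- remove_outliers(tab, "area")
fit <- fit_lme(tab, "area")
fit$effects                       # ecotype / time / interaction tests
head(tukey_pairwise(fit, "ecotype"), 3)

pca_per_timepoint(tab, das = 17)
relieff_rank(tab[tab$das == 17, descriptor_names()],
             tab$ecotype[tab$das == 17])
```

The README shows the same pipeline with the numbers it prints.
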