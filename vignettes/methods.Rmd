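---
title: "Methods: colorimetric phenotyping and TCC prediction in carophen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colorimetric phenotyping and TCC prediction in carophen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carophen)
```

# Scope and model

`carophen` turns photographs of cassava root slices into six colorimetric
indices and predicts total carotenoid content (TCC, µg per g fresh weight)
from them. The underlying biology is simple: β-carotene, the dominant
cassava carotenoid, absorbs blue light, so carotenoid-rich pulp is yellow.
In CIELAB coordinates that shows up almost entirely on the blue–yellow b*
axis and its induced polar magnitude, chroma; everything downstream —
correlation screens, diversity clustering, and the prediction benchmark —
is built around that one strong signal plus several weaker ones.

# The colorimetry chain and how ambiguities were resolved

The conversion is the classical three-step chain: per-channel scaling of
0–255 RGB to a linear 0–100 range, the 3×3 tristimulus matrix to XYZ, and
the CIELAB transform

$$L^* = 116\,f(Y/Y_n) - 16,\quad
  a^* = 500\,[f(X/X_n) - f(Y/Y_n)],\quad
  b^* = 200\,[f(Y/Y_n) - f(Z/Z_n)],$$

with $f(q) = q^{1/3}$ for $q > 0.008856$ and $f(q) = 7.787q + 16/116$
otherwise. Several details of the source equations required interpretation;
each choice is configurable and audit-tested:

* **Linearization.** The typeset scaling formula,
  `((v + 0.055)^2.4 / 1.055) × 100` with `v = V/255`, maps white to 107.78
  and therefore violates the L* ∈ [0, 100] contract stated alongside it. We
  treat it as a typographical corruption of the standard sRGB companding law
  `((v + 0.055)/1.055)^2.4 × 100` (with the linear toe below v = 0.04045),
  which maps white to exactly 100. The literal formula is retained as
  `dialect = "as_printed"` so the corruption is reproducible on demand.
* **Hue.** The typeset hue formula applies a (co)sine to a ratio and
  switches cases on a sign. The only reading consistent with the published
  group means (hue ≈ 105.6° at a* = −10.23, b* = 36.48) is
  `arccos(a*/chroma)` reflected to `360° − ·` when b* < 0 — identical to
  `atan2(b*, a*)` mapped to [0°, 360°). Chroma is the Euclidean norm
  `sqrt(a*² + b*²)` (the "mean of a* and b*" phrasing is not a mean; the
  norm reproduces 37.93 from (−10.23, 36.48)). At chroma ≈ 0 the hue is
  undefined and returned as 0 with an explicit flag.
* **White point.** The stated D65/10° white (94.83, 100, 107.38) is
  inconsistent with the row sums of the stated RGB→XYZ matrix
  (95.75, 100, 108.90). We default to the stated white, which makes a
  neutral gray map to small nonzero a* (+1.61 at white) and b* (−0.94);
  passing the row sums as the white point restores an exactly neutral gray
  axis. Both are tested.
* **Piecewise seam.** With the printed constants 7.787 and 16/116 the two
  branches of $f$ differ by ≈ 3·10⁻⁷ at the threshold — continuous to well
  within 10⁻⁶ on the f scale, which is what the test asserts.

The 0–240 **lightness** index, `(max(R,G,B) + min(R,G,B))·240/(2·255)`
averaged per pixel, is a separate brightness measure and must not be
confused with L*. All conversions accept real-valued channel means, since
foreground means of pixels are fractional. `lab_to_rgb()` is the exact
algebraic inverse of the forward chain under the standard dialect; colors
whose inverse leaves [0, 255] are rejected naming the offending channel.

# Imaging

The phenotyping platform photographs six ~2 cm root slices on a blue liner.
The source protocol names no segmentation rule, so the package uses the rule
the liner exists to enable: a pixel is background when
`B − max(R, G) ≥ margin` (default 30 channel units); the complement is the
root mask after removing connected components smaller than `min_area`
(default 50 px) and filling enclosed holes. The rule is invariant to adding
a constant to all channels, and on synthetic images with known truth masks
it recovers the mask exactly at zero jitter and to ≥ 99 % at default jitter.
An empty mask is a hard error ("no root detected"), never a silent empty
result.

Replicates (three images of six pieces in the source protocol) are averaged
at the level of per-image colorimetric records, not raw pooled pixels, to
match "each record is an average of measurements"; a switch at the caller's
level (compute one record per image, then `aggregate_replicates()`) makes
the pooling order explicit. Hue is averaged circularly via the mean
resultant vector — arithmetic averaging of 359° and 1° would give 180°.
Note the polar identity chroma = √(a*²+b*²) holds for records computed from
pixels but not, in general, for aggregated records; the constructor tracks
this. Gaussian smoothing defaults to σ = 2 px at the native 3264-px capture
width and can be rescaled proportionally for smaller rasters
(`scale_to_width`).

# Assay

TCC is computed exactly as `A·V·10⁴ / (E·P)` with E = 2592, the extinction
coefficient of β-carotene in petroleum ether. Duplicate samples per genotype
are averaged after conversion (the source takes two; it does not state how
they were combined). The synthetic assay generator inverts the formula, so
the noiseless round trip is exact to machine precision.

# The synthetic world

No raw images or genotype tables are distributable, so the package carries
a generator whose defaults *are* the published panel structure: five groups
of 76/34/26/21/71 genotypes with mean TCC 1.91/1.82/4.82/10.74/3.60 µg g⁻¹
and the published group-mean colorimetric indices where they exist (groups
3–5 and the high-TCC group 4: L* 76.14, a* −12.38, b* 55.57, lightness
136.04). Groups 1 and 2 have no published color means beyond "low b*,
highest L*, lightness and hue"; the defaults (b* 17 and 21, L* 79.5,
lightness 182 and 185, a* −6.5 and −4.0) honor those orderings and make the
two groups separable at low noise.

The generative model is the simplest structure consistent with the
published marginal correlations:

* TCC per group: Gaussian, truncated below at 0.05 µg g⁻¹ (all published
  values are ≥ 0.30; negatives are non-physical).
* b*, a*, L*: affine in the TCC deviation from the group mean plus
  independent Gaussian noise. Slopes (4.213, −0.859, 0.4 per µg g⁻¹) are
  the least-squares fit through the published group means.
* chroma and hue: always computed from a* and b*, never drawn.
* lightness: affine in the TCC deviation (−5.0 per µg g⁻¹) and in the L*
  deviation (+1.0) plus noise, clipped to [0, 240]. (A lightness driven by
  L* alone cannot reproduce the published strong negative TCC–lightness
  correlation, so TCC enters directly.)

Within-group standard deviations are not published. They were fixed once,
a priori, by moment algebra on the five-group mixture: with group TCC sds
(0.70, 0.65, 1.00, 1.40, 0.90) the mixture variance of TCC is 7.06; setting
the color-noise sds to 4.7 (b*), 3.3 (a*), 5.0 (L*) and 14.0 (lightness)
makes the population correlations r(TCC, b*) = 0.90, r(TCC, a*) = −0.50,
r(TCC, lightness) = −0.66 and r(TCC, L*) ≈ −0.14 (not practically
significant), matching the published screen. The tests verify the realized
correlations against an independent re-simulation oracle, not against these
derivations. A single `noise_scale` multiplier shrinks every sd for
recovery tests ("low noise" = 0.1); it defaults to 1 and is never used to
tune an outcome.

Synthetic root-slice images paint `n_pieces` disjoint ellipses of the pulp
color obtained by `lab_to_rgb()` on a saturated blue liner
(RGB 25/60/230), with per-pixel Gaussian jitter (default sd 6 on pulp, 8 on
the liner) and integer quantization. The truth mask and generating record
are stored. What the generator does **not** emulate: root texture and
vascular rings, specular highlights, uneven illumination, camera response
differences, or JPEG artifacts. A green segmentation or recovery test
therefore establishes correctness of the algorithms on separable-color
imagery, not robustness to field-quality photographs.

# Diversity analyses

Variables are standardized to unit variance before PCA and k-means — the
alternative lets the 0–240 lightness scale dominate µg g⁻¹ TCC. K-means uses
25 restarts and a caller-supplied seed; cluster labels are canonicalized by
descending mean TCC so "cluster 1" is always the highest-TCC group (the
published grouping numbers its highest-TCC group 4; the Rand index used for
recovery scoring is label-invariant, so nothing depends on the numbering).
Clustering on PCA scores instead of raw standardized variables is available
(`on = "pca"`); with all components retained the two are rotations of each
other.

The elbow curve reports the within-group sum of squares for k = 1..k_max
with a knee diagnostic: the maximum discrete curvature of the curve
relative to the total sum of squares, flagged "no clear elbow" below 0.08.
That constant separates an isotropic Gaussian blob (≈ 0.04) from clustered
generator output (≥ 0.12) across settings; it is a reporting aid, never an
enforcement — the user confirms k. Group contrasts are one-way ANOVA with
Tukey HSD at α = 0.05 and an insert-and-absorb compact letter display.

# Prediction benchmark

Twelve learners are benchmarked. Environment dictated the build-vs-buy
split: stepwise linear models ride on `stats::step` (AIC), ridge on
`glmnet`; the regression tree, bagged forest, NIPALS PLS, Bayesian lasso
(Park–Casella Gibbs sampler), its spike-and-slab model-averaged variant,
the single-hidden-layer network (BFGS on the penalized least-squares
objective), and the kernel ε-SVR (Huber-smoothed primal, RBF kernel with a
median-heuristic bandwidth) are implemented in-package, since no suitable
implementations exist in the supported dependency set. Defaults, chosen
once: ANN 5 tanh units, weight decay 0.01, standardized inputs and target,
2 restarts; SVM cost 10, ε 0.1; RF 500 trees, mtry = ⌊p/3⌋; CART
minimum split 10, depth ≤ 8, split gain ≥ 0.5 % of root SS; PLS components
by internal 5-fold CV up to 6; Gibbs samplers 1500 iterations, 500 burn-in.
The two Bayesian variants are genuinely different estimators: BL predicts
from the posterior-mean coefficients of the Bayesian lasso; BBL averages
predictions over spike-and-slab inclusion states (the source names both
without defining them, so this package defines them explicitly).

**Validation designs.** V-Random: repeated stratified 80/20
train/validation splits. IV-Random: 60/20/20 with a held-out test set;
metrics are recorded on both the validation and test partitions (the source
is ambiguous about which its table reports; summaries here use test).
IV-Cluster: each cluster in turn is the test set and the remaining clusters
are split 80/20. Stratification is on TCC quintiles with exact global
partition sizes. The source states "5-fold increase and 6 repetitions" in
one place and "5 repetitions of 6-fold" in another; the package generates
6-fold × 5-repetition inner-resampling assignments with every plan (both
numbers configurable) and 30 outer repeats by default. Tests and the
acceptance script run 3 outer repeats and RF at 150 trees purely as runtime
scaling; nothing else is reduced.

**Metrics.** Two R² columns are always reported: `r2`, the
explained-variation ratio Σ(ŷ−ȳ)²/Σ(y−ȳ)² as conventionally printed, and
`r2_cor`, the squared Pearson correlation. The printed ratio can exceed 1
for biased predictions and — more importantly — is not a skill measure: a
model predicting pure noise has Σ(ŷ−ȳ)² > 0. Bound-type checks (the
permutation-leakage criterion "shuffled TCC ⇒ validation R² ≤ 0.1", the
IV-Cluster < IV-Random ordering) therefore use `r2_cor`. RMSE is in µg g⁻¹;
MAPE is a fraction (0.05 = 5 %), with zero observations excluded and warned
about. Predictions are never clipped to positive TCC; negative linear
predictions are reported as-is.

**Importance and reduced models.** Relative importance is rescaled so the
top feature is 100: |t| of retained terms for the stepwise family,
|standardized coefficients| for ridge/BL/BBL, VIP loading-weight scores for
PLS, summed split variance reduction for CART/RF, and permutation importance
(refit on 80 % of the training rows, permute on the held-out 20 %) for ANN
and SVM — computed strictly inside the training partition, so feature
selection can never see validation or test rows. The reduced model keeps
features with importance ≥ 50 % (never empty: top-1 fallback with a
warning), is refitted, and compared to the complete model by a two-sided
paired t-test on per-repeat R².

A note on exactness: on exactly linear data the selection-based linear
family and full-rank PLS recover the law to RMSE < 10⁻⁸; ridge and the
Bayesian shrinkage learners are biased by construction and are deliberately
excluded from that exactness contract.

# Numerical and degenerate-input policy

TCC truncation at 0.05 µg g⁻¹; lightness clipped to [0, 240]; L* clipped to
[0, 100] in the generator; hue wrap-around at 360° snapped to 0; chroma = 0
flagged rather than producing NaN hue; constant columns rejected by PCA and
flagged undefined by the correlation report; constant observations make R²
an error, not a NaN; empty k-means clusters trigger internal restarts and
only then an error; per-cell benchmark failures are warned and skipped, not
fatal to the grid; k = n clustering returns the trivial partition with zero
within-SS.

# Known limitations

* The generator's affine-Gaussian color model reproduces first and second
  moments, not the full shape of real panels (e.g. skewness of TCC within
  the high-carotenoid group, genotype-by-environment effects).
* Synthetic imagery is colorimetrically faithful but photometrically naive
  (see above); segmentation performance on real photographs will be
  dominated by illumination control, which the package does not model.
* MAPE on the synthetic panel is much larger than on tightly calibrated
  laboratory data because the generator's noise floor is a larger fraction
  of low TCC values; comparisons of MAPE across datasets are therefore not
  meaningful.
* The kernel SVR solves a smoothed primal rather than the exact
  ε-insensitive dual; solutions are near-identical for the panel sizes used
  here but are not sparse in support vectors.
* No ICC profiles, chromatic adaptation, or ΔE color-difference metrics;
  device calibration is identity (slope 1, intercept 0).
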