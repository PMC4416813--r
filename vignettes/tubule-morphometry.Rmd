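---
title: "Livewire morphometry of seminiferous tubules: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Livewire morphometry of seminiferous tubules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubulemorph)
```

`tubulemorph` measures seminiferous tubule cross-sections in stained testis
micrographs. This vignette explains the segmentation model, the geometry
definitions, the synthetic-data generators, and the statistical layer — and
records the design choices made where several reasonable options existed.

## The segmentation model

A tubule boundary is traced as a sequence of globally optimal paths over
the 8-connected pixel graph (the livewire / intelligent-scissors idiom).
The cost of stepping from pixel $p$ to an adjacent pixel $q$ is

$$c(p,q) = w_z f_z(q) + w_c f_c(q) + w_G f_G(q) + w_D f_D(p,q),$$

with default weights $(4, 4, 1, 1)$. The four features:

* $f_z$ — Laplacian-of-Gaussian **zero-crossing** map, 0 on a crossing
  pixel and 1 elsewhere. A crossing requires a sign change towards a
  4-neighbour *and* a Laplacian jump larger than `zc_slope_frac` (default
  0.75) times the mean absolute Laplacian; without the slope gate, sensor
  noise in flat regions would mark spurious crossings everywhere.
* $f_c$ — **Canny** edge map, 0 on an edge pixel. Gaussian smoothing,
  non-maximum suppression along the quantized gradient direction, then
  hysteresis with thresholds `canny_low`/`canny_high` (defaults 0.1/0.2)
  expressed as fractions of the maximum gradient magnitude.
* $f_G$ — gradient magnitude, min–max normalized and inverted
  ($1 - G/G_{\max}$) so that strong edges are cheap. For RGB input the
  magnitude and direction come from the multichannel **vector gradient**:
  the leading eigenvalue/eigenvector of the structure tensor summed over
  channels, which reduces exactly to the scalar gradient when the channels
  are identical and still sees color edges that cancel in the luminance.
  The binary detectors operate on the luminance channel.
* $f_D(p,q) = \tfrac{2}{3\pi}\left[\arccos d_p + \arccos d_q\right]$ — the
  gradient-**direction** cost, where $d_p, d_q$ are inner products of the
  edge-tangent unit vectors at $p$ and $q$ with the unit link vector,
  orientation-normalized so $d_p \ge 0$. It lies in $[0,1]$, vanishing when
  the step follows the local edge tangent. Where the gradient is exactly
  zero the tangent is the zero vector and $f_D = 2/3$, a neutral value.

The binary features are coded 0 = edge so that the weighted sum is
*minimized* along boundaries; the weights are used exactly as printed above
even though they do not sum to one, and they are configurable. Diagonal
links are scaled by $1/\sqrt2$ by default (`diagonal_scaling`), the common
practice in interactive-scissors implementations; switching the flag off
applies the formula literally to all eight neighbours, and both modes are
exercised by the tests.

Three numerical choices make results reproducible run-to-run: nodes are
settled in order of (cost, linear pixel index), predecessors are updated on
strict improvement only with neighbours enumerated in a fixed order, and
seed lists are canonicalized to counter-clockwise orientation before
tracing. The last point matters because $c(p,q) \ne c(q,p)$ (the feature
terms are evaluated at the destination), so without canonicalization a
clockwise seed list could legitimately pick a different equal-cost pixel
here and there. Images are processed with reflect padding so the border
itself never generates spurious edges.

Interactivity is replaced by a scripted seed-list API: ordered `(row, col)`
pixels (0-based, origin top-left) per tubule, optionally with a second list
for the lumen. The computation is identical to the interactive loop — each
click fixes the optimal segment from the previous seed.

## Geometry definitions

For a closed traced contour:

* **Area**: the number of pixels inside the drawn boundary, boundary pixels
  included (the drawn boundary sits *on* the tubule's outer edge, so
  excluding it would bias small tubules low), times `pixel_size`² · 10⁻⁶
  mm². Interiors are filled by hole-filling, equivalent to the even–odd
  rule for a simple contour.
* **Diameter**: twice the mean Euclidean distance from boundary pixels to
  the centre of mass of the *filled interior* (not of the boundary pixels:
  the interior centroid is robust to uneven seed spacing along the
  boundary).
* **Epithelial height**: the symmetric mean nearest-boundary distance
  between tubule and lumen outlines — average of the outer→lumen and
  lumen→outer directed means, so the result does not depend on which
  contour is sampled more densely. Distances come from an exact Euclidean
  distance transform of one boundary sampled at the other. Tubules without
  a visible lumen carry an absent height (`has_lumen = FALSE`), never an
  imputed value.

The μm-per-pixel calibration is always supplied explicitly (config or
`--pixel-size`); it is never read silently from image metadata.

## What the phantoms emulate — and what they do not

`render_phantom()` draws a stylized stained cross-section: bright pink
interstitium, darker annular epithelium, pale lumen, optional ellipticity,
additive Gaussian noise and a low-frequency texture field. Interfaces are
rendered with a one-pixel anti-aliased blend, emulating optical blur; this
makes the sub-pixel location of the gradient maximum coincide with the
analytic boundary, so the analytic geometry (area $\pi r^2$, diameter $2r$,
height $r_\text{outer} - r_\text{lumen}$) is the correct ground truth for a
traced contour. Default radii and heights sit at the scale observed in mink
testis sections (outer diameters roughly 490–565 μm, epithelial heights
160–280 μm at 1 μm/px).

The phantoms are deliberately *not* a generative histology model: no cell
nuclei, no stain variability, no autolysis texture, no out-of-focus
regions. The algorithms under test consume edges, and the phantoms provide
controlled edges with known truth. Passing the recovery tests therefore
demonstrates correctness of the segmentation/measurement machinery on
well-formed boundaries at realistic scale and noise — it does not certify
performance on degraded tissue, where seed placement and operator judgment
dominate.

`simulate_study()` draws tubule-level endpoints as group mean + animal
random effect + tubule noise, and one gross value per animal. The default
design is six groups (delays of 0, 6, 18, 30, 42 h and 6 h + freezing) of
five animals, thirty tubules per animal, with group means set to the
observed endpoint means of the emulating study. The published tables report
only group-level standard errors (≈ 0.014 mm², 18 μm and 12 μm for area,
diameter, epithelial height), which constrains only the variance of animal
means, $\sigma_b^2 + \sigma_w^2/m$; the split between animal and tubule
components is not identified. The default takes $\sigma_b = \sigma_w$
calibrated to the published standard errors (e.g. 26.4 μm each for
epithelial height), and the partition is configurable, never inferred. All
randomness flows from one integer seed; sub-streams (texture, noise,
tubule table, gross table) are split off by fixed documented offsets.

## The statistical layer

The animal is the experimental unit throughout.

* **One-way ANOVA** for gross endpoints: classical between/within
  decomposition, $F = MS_B/MS_W$ on $(k-1, N-k)$ df, group standard errors
  $\sqrt{MS_W/n_g}$.
* **Hierarchical ANOVA** for tubule endpoints: fixed group effect, random
  animal-within-group effect. Balanced data use the closed form
  $F = MS_\text{group}/MS_\text{animal(group)}$ with denominator df
  $N_\text{animals}-k$; unbalanced data (unequal tubule counts, as real
  acquisitions produce) use the classical unbalanced nested sums of squares
  with a Satterthwaite-combined denominator mean square and Satterthwaite
  df. Group means are means of animal means; group standard errors are on
  the animal-mean scale. No imputation of missing tubules.
* **Kenward–Roger** denominator-df adjustment is deliberately not
  implemented: it requires full REML machinery disproportionate to a
  balanced 5-animal design, and for balanced data the dfs coincide with the
  closed form (the tests confirm agreement with an REML mixed-model fit).
* **Tukey** pairwise correction via the studentized-range distribution on
  the model's denominator df, Tukey–Kramer standard errors for unequal
  group sizes; two groups reduce exactly to the pooled t-test.
* **Compact letter display** by insert-and-absorb: groups share a letter
  exactly when their adjusted p exceeds α (default 0.05).

Degenerate inputs are handled explicitly: identical values everywhere give
$F = 0, p = 1$; zero residual variance with distinct means gives
$F = \infty, p = 0$ and fully distinct letters; a single tubule per animal
reduces the hierarchical model exactly to the one-way model; groups with
fewer than two animals, or an animal appearing in two groups, are errors
naming the offender.

## Problem sizes and verification

The test-suite and acceptance computations use: 100 random 32×32 cost
fields checked bit-exactly against an independent textbook Dijkstra; 50
random link-cost evaluations against an independently coded weighted sum;
20 annulus phantoms with outer radii 55–110 px and noise up to ~10 % of
the epithelium–interstitium contrast (recovery bounds: area 2 %, diameter
1 %, height 3 %); 2000 null simulations of the 5×5×30 design for type-I
calibration and 1000 for Tukey familywise error, both judged against the
exact binomial 99 % interval around 0.05.

The recovery of the published epithelial-height effect (group means
161.8/282.4/256.8/280.0/245 μm, animal-mean SE ≈ 12 μm) is a sharp case:
the true probability that a 5×5×30 experiment rejects at α = 0.001 *and*
the letter display separates the 0 h group from all others is about 95.5 %
(measured at 20 000 replicates) — barely above the 95 % requirement. At 500
replicates the Monte-Carlo error (±0.9 %) cannot resolve that comparison,
so the package measures the same quantity at 8000 replicates (Monte-Carlo
s.e. ≈ 0.23 %) against the unchanged 0.95 threshold.

## Known limitations

* The livewire quality is bounded by seed quality; the scripted API places
  seeds on known boundaries, while real use inherits operator variance.
* The direction cost makes link costs asymmetric; canonicalizing seed
  orientation restores determinism but means a traced boundary is defined
  as the counter-clockwise optimum.
* The unbalanced hierarchical path is a moment-based approximation; with
  severe imbalance its F can differ noticeably from an REML fit, though
  the inferential conclusions agree in the tested regimes.
* Phantom ellipticity uses a first-order signed-distance rendering; for
  strongly elliptical tubules the ground-truth height is computed
  numerically rather than in closed form.
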