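# tubulemorph

Semi-automatic morphometry of seminiferous tubules in stained testis
micrographs, with the statistics used for testicular endpoints in
toxicologic and environmental-monitoring pathology.

Histopathology of the testis is the most sensitive readout of male
reproductive toxicity, and quantitative endpoints — tubular area, tubular
diameter, epithelial height — are measured on micrographs of stained
cross-sections. Outlining hundreds of tubules by hand is slow and
subjective. `tubulemorph` implements the livewire (intelligent-scissors)
approach: the user (or a script) supplies a few seed points on a tubule
boundary and the globally optimal minimum-cost path over the pixel graph
fills in the rest of the outline with pixel precision.

## Method

For each pixel, four edge measures are computed: a Laplacian zero-crossing
map `f_z`, a Canny edge map `f_c` (both 0 on an edge pixel, 1 elsewhere),
the inverted normalized gradient magnitude `f_G = 1 − G/G_max`, and the
gradient direction. For color images the gradient is the multichannel
vector gradient (leading eigenvector of the local structure tensor summed
over channels). These are combined into the link cost between 8-adjacent
pixels `p`, `q`:

    c(p, q) = 4 f_z(q) + 4 f_c(q) + f_G(q) + f_D(p, q)

where `f_D(p,q) = (2/3π) [arccos d_p(p,q) + arccos d_q(p,q)]` is the
intelligent-scissors gradient-direction cost: it vanishes when the path
follows the local edge tangent and is maximal when it cuts across a strong
edge. Dijkstra's algorithm finds minimum-cost boundaries between ordered
seed points; concatenated segments form a closed contour.

From a closed contour: **area** is the number of pixels inside the drawn
boundary (converted by the μm/px calibration to mm²); the **radius** is the
mean distance from boundary pixels to the centre of mass of the interior;
the **epithelial height** is the symmetric mean nearest-boundary distance
between the tubule outline and the lumen outline (absent when no lumen is
visible).

The statistical layer mirrors the endpoints' study design, the animal being
the experimental unit: one-way ANOVA for gross endpoints (one value per
animal), hierarchical ANOVA (fixed group effect, random animal-within-group
effect) for tubule-level endpoints — `F = MS_group / MS_animal(group)` on
`(k−1, N_animals−k)` df for balanced data, Satterthwaite-combined
denominator otherwise — with Tukey-adjusted pairwise comparisons and a
compact letter display.

A phantom generator renders stylized stained cross-sections (bright
interstitium, dark annular epithelium, pale lumen) with analytic ground
truth, and a study simulator draws animal- and tubule-level endpoints at
configurable effect sizes, so segmentation, morphometry and statistics are
all testable without real tissue.

## Worked example

```r
library(tubulemorph)

# a phantom with one tubule: outer radius 110 um, lumen 55 um, 1 um/px
spec <- phantom_spec(size = c(320L, 320L), pixel_size = 1,
                     tubules = data.frame(center_r = 160, center_c = 160,
                                          outer_um = 110, lumen_um = 55),
                     noise_sd = 0.02, seed = 7)
ph    <- render_phantom(spec)
stack <- compute_feature_stack(ph$image)
outer <- trace_closed_contour(phantom_seeds(spec, 1, 16, "outer"), stack)
lumen <- trace_closed_contour(phantom_seeds(spec, 1, 12, "lumen"), stack)
measure_tubules(outer, lumen, pixel_size = 1, tubule_id = "t1")
#>   tubule_id area_mm2 diameter_um epithelial_height_um has_lumen pixel_size
#> 1        t1 0.038335    220.0313             54.62932      TRUE          1
```

The analytic truth is area `π·110²·10⁻⁶ = 0.03801` mm², diameter 220 μm,
height 55 μm: the traced measurements land within 0.9 %, 0.02 % and 0.7 %.

Statistics on a simulated six-group study (five animals per group, thirty
tubules per animal):

```r
sim <- simulate_study(study_design(seed = 5))
tab <- data.frame(animal_id = sim$tubules$animal_id,
                  group = sim$tubules$group,
                  value = sim$tubules$epithelial_height_um)
fit <- letter_display(tukey_pairwise(nested_anova(tab)))
fit
#> Hierarchical ANOVA: F(5, 24) = 11.43, p = 1.005e-05
fit$letters
#>        0h        6h       18h       30h       42h 6h+frozen
#>       "a"       "b"       "b"       "b"       "b"       "b"
```

The immediately-fixed group separates from every delayed/frozen group
(letter `a` against `b`), reflecting the designed epithelial-height effect.

The shell pipeline (`features`, `trace`, `measure`, `simulate`, `stats`) is
in `inst/cli/tubulemorph`; seeds, contours, measurements and results travel
as CSV, configuration as a flat `key = value` file, and the two model
variants (time model over the delay groups; freeze model over 0 h, 6 h,
6 h + frozen) are selected with `--groups`.

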