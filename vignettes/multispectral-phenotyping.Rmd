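---
title: "Methods: plant-level phenotyping from multispectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant-level phenotyping from multispectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomspec)
```

## The measurement problem

A four-band multispectral camera (green 550 nm, red 660 nm, red edge
735 nm, near-infrared 790 nm) photographs individual potted plants from
0.7–1.4 m. Healthy leaf tissue reflects strongly in the NIR and absorbs
in the red, so spectral indices built from these bands separate plant
from soil, pot and floor, and summarize vigor. Because fertilization
affects early growth mostly through *size and shape* rather than
reflectance, the pipeline extracts both: per-plant means of eleven
vegetation indices and twelve binary shape descriptors, tracked weekly
and compared across fertilization treatments (T0 = control up to T3 =
recommended dose, six replicate plants each).

## Pre-processing

The camera's four lenses are physically offset; designed for >30 m
flight altitude, they produce visibly displaced band images at close
range. Displacement is corrected by **integer pixel shifts** of the
green, red-edge and NIR bands onto the red reference
(`align_bands()`). The default profile (green `[50, 23]`, NIR
`[41, -34]`, red edge `[68, -11]`, read `[dx, dy]` with dx along the
column axis and dy along the row axis) is a one-off calibration from a
scene with a reference point; `estimate_shift()` automates that
calibration by exhaustive integer cross-correlation within a
±`max_shift` window. The correlation surface is evaluated by FFT on
zero-padded, mean-centred images — algebraically the same sums of
products the explicit double loop would compute, with no wraparound
inside the window — and the argmax is returned as the *corrective*
shift, directly usable as a profile entry. A normalized peak below 0.3
flags the estimate as low confidence.

Pixels exposed at the borders by shifting are set to `NA` rather than
any fabricated reflectance, so they can never leak into index
statistics. The standard area of interest (`aoi()`, rows 200:900 ×
columns 200:1000, half-open) crops a 960 × 1280 frame to 700 × 800 and
removes those borders entirely, since all calibrated shifts are below
the 200 px margin. Sub-pixel registration, rotation and lens-distortion
models are deliberately out of scope: at these working distances the
residual after integer translation is below the segmentation scale.

Integer TIFF inputs are rescaled to [0, 1] by the type maximum (255 or
65535). Any fixed monotone rescale leaves the percentile segmentation
and the normalized indices unchanged; [0, 1] is chosen for
interpretability. Inputs are treated as already radiometrically
calibrated; sunshine-sensor correction is upstream of this package.

## Vegetation indices

Eleven per-pixel indices are computed from the registered bands
(G, R, E, N):

| Index | Formula | Index | Formula |
|---|---|---|---|
| NDVI | (N−R)/(N+R) | MSR | (N/R − 1)/(√(N/R) + 1) |
| GNDVI | (N−G)/(N+G) | SR | N/R |
| RENDVI | (N−E)/(N+E) | NDRER | (E−R)/(E+R) |
| NLI | (N²−R)/(N²+R) | SPI2 | (N−G)/(N−R) |
| OSAVI | 1.5(N−R)/(N+R+0.16) | LCI | (N−E)/(N+R) |
| GRVI | N/G | | |

Two of these circulate in typographically corrupted printed forms: MSR
without the square root (which collapses to a monotone transform of SR
and would carry no extra information) and NLI with the red-edge band in
the denominator. The canonical literature forms above are the default;
the literal variants are available with `formulas = "as-printed"` so
the difference can be inspected. Zero denominators and undefined
inputs yield `NA`, never infinities, and `NA` pixels are excluded from
every downstream statistic (`masked_mean()` drops them from numerator
and denominator alike).

## Segmentation

The plant is extracted from the NDVI image by a data-driven histogram
rule rather than a fixed threshold, which travels poorly across
backgrounds and lighting:

1. **Gate**: candidate pixels are those with NDVI strictly above
   `min_index` (default 0.1, excluding soil/background near zero). The
   gate is applied as a hard precondition of the percentile step — the
   most literal reading of the rule.
2. **Percentile cut**: the top `keep_fraction` (default 0.92) of the
   candidate NDVI distribution is retained. Quantiles use linear
   interpolation of order statistics (R type 7); ties at the cut are
   retained, so a noiseless plant whose pixels share one NDVI value is
   kept whole.
3. **Largest component**: 8-connected component labelling keeps only
   the largest object, eliminating speckle. Equal sizes are broken
   deterministically in favour of the component containing the
   lexicographically smallest (row, col) pixel.

An NIR-only threshold strategy is included (`strategy = "nir"`) for
comparison, but bright non-plant surfaces defeat it; it is not the
default. Scenes with no candidate pixels return an empty mask with a
warning, and the pipeline records `NA` feature rows for them instead of
aborting — senescent (yellow/brown) leaves reflect differently and may
be under-segmented, a known limitation of the NDVI rule.

## Morphological descriptors

Twelve descriptors of the binary mask, with the classic `regionprops`
semantics:

* **Area, FilledArea, ConvexArea** — pixel counts of the mask, the mask
  after hole filling (background flood-filled from the border,
  4-connected), and the rasterized convex hull of pixel centres.
* **Extent, Solidity** — area over bounding-box area and over convex
  area.
* **EquivDiameter** — √(4·Area/π), the equal-area circle's diameter.
* **EulerNumber** — objects minus holes (8-connected objects,
  4-connected holes).
* **MajorAxisLength, MinorAxisLength, Eccentricity, Orientation** — from
  the ellipse with the same normalized second central moments as the
  region, each pixel treated as a unit square (+1/12 variance term), so
  a single pixel has positive axis lengths (≈1.1547 px). Orientation is
  measured from the column axis, counter-clockwise positive with the
  row axis flipped (y up), in (−90°, 90°]. Moments use the unfilled
  mask.
* **Perimeter** — the length of the closed 8-connected boundary chain
  (Moore tracing with Jacob's stopping criterion): 1 per axis step, √2
  per diagonal step. A 10 × 10 square has perimeter 36; a single pixel
  0.

Numerical notes. The chain-length perimeter overestimates a smooth
boundary by a few percent (≈5% for a digitized disk of radius 50) and
is *resolution dependent*: nearest-neighbour upscaling by k multiplies
it by slightly more than k, because diagonal steps become unit-step
staircases. Area, axis lengths, extent and solidity scale as expected.
These are properties of the convention, shared with the original
implementations it mirrors, and the tests assert them as such.

## Statistics

* `anova_oneway()` — classical fixed-effects one-way F test from the
  sum-of-squares decomposition (identical-data edge case reported as
  F = 0, p = 1).
* `tukey_hsd()` — all pairwise comparisons on the studentized range
  distribution with pooled variance (Tukey–Kramer for unequal sizes),
  default alpha 0.01 ("99% confidence"). Applied per week and pooled;
  no omnibus gating, and no multiple-testing correction across
  variables (deliberately, matching the analysis design it reproduces;
  the randomized-block structure is likewise not modelled — a noted
  limitation).
* `fit_growth_regression()` — degree-1/2 polynomial least squares with
  R² = 1 − SSres/SStot. Fits are to per-week treatment means by
  default, with plant-level fitting available by passing replicate
  data; constant responses report R² = 0 with a warning.
* `functional_boxplot()` — trajectories ranked by modified band depth
  (all unordered pairs, proportion-of-timepoints inside the pair band);
  the deepest half forms the central band, curves escaping the band
  inflated 1.5× its height are outliers, and the outer envelope is the
  pointwise range of the non-outliers. A simpler pointwise-deviation
  depth is available via `depth = "pointwise"`.
* `summarize_boxplot()` — type-7 quartiles with 1.5 IQR whiskers
  (convention documented because it matters at n = 6).

## The synthetic generator

`generate_scene()` renders a star-convex lobed blob — radius
r(θ) = r₀(1 + a·sin kθ), default a = 0.25, k = 7 — chosen because it is
cheap, its analytic area π r₀²(1 + a²/2) is known, and its lobes make
hull and solidity non-trivial. Plant reflectances default to
(G, R, E, N) = (0.12, 0.06, 0.35, 0.55), i.e. NDVI ≈ 0.80, against a
flat background of (0.18, 0.20, 0.20, 0.20), NDVI = 0. Bands can be
independently displaced by programmed integer shifts (to exercise
registration) and carry seeded additive Gaussian noise (default
sd 0.01). The ground-truth mask is the un-shifted blob support.

`generate_trial()` draws value(plant, week) =
model_treatment(week)·(1 + ε), ε ~ N(0, CV²), CV 0.10, for six
replicates over weeks 0–7 — 192 records per variable. The default
per-treatment weekly models (`growth_models()`) are the package's
reference parameterization of seven size descriptors for T0 and T3;
T1/T2 default to dose-weighted blends (weights 6.25/25 and 12.5/25)
since only the extreme treatments have reference curves. Noise is
multiplicative because growth scatter is proportional to plant size.

What the generator does *not* emulate: radiometric vignetting, soil
texture, leaf-level 3-D structure, specular highlights, senescent
tissue. Passing tests therefore demonstrate algorithmic correctness on
controlled inputs, not robustness to every field condition.

A property worth knowing when interpreting simulated trials: the
reference T0 (linear) and T3 (quadratic) Area curves **cross near week
4** — the control curve starts higher and the fertilized curve
overtakes it. Near the crossing the true treatment difference is a
fraction of a percent of the mean, so no test at six replicates and
10% CV can detect it there; T0/T3 separation under these defaults is
reliably detectable in the early weeks before the crossing and from
week 6 onward, and that is exactly what the test suite asserts and
what the acceptance checks report. Coefficient recovery is verified at
the replicate level (48 points per treatment), where the 3-standard-
error criterion has its nominal coverage; with 8 weekly means the
heavier t tails at 5–6 residual degrees of freedom already push the
joint pass rate below 90% even for a perfectly specified model.

## Problem sizes and determinism

Tests run on scenes from 120 × 150 up to a single full 960 × 1280
frame, 50 seeded random blobs for the morphology oracles, 10⁶ random
band pairs for the index-bound fuzz, and 100 seeded trial replications
for parameter recovery — sizes chosen so the whole suite exercises
every code path in well under a minute per file. All randomness flows
from explicit seeds; the pipeline writes a config-hash provenance
sidecar, and re-running on identical inputs is byte-identical (feature
values are serialized at 17 significant digits).
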