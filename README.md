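# phenomspec

Plant-level phenotyping from close-range multispectral images, in R.

Greenhouse and robotic crop-monitoring rigs photograph individual plants
with a four-band camera — green (550 nm), red (660 nm), red edge
(735 nm), near-infrared (790 nm). **phenomspec** turns those per-band
TIFF frames into per-plant, per-week measurements and
treatment-discrimination statistics:

1. **Registration** — the four lenses are physically offset at close
   range; bands are co-registered onto the red reference by calibrated
   integer pixel shifts (`align_bands()`, automated calibration via
   `estimate_shift()`), then cropped to a fixed area of interest
   (`clip_aoi()`, 960 × 1280 → 700 × 800).
2. **Vegetation indices** — eleven per-pixel indices
   (`compute_all_indices()`), led by
   NDVI = (ρ<sub>NIR</sub> − ρ<sub>RED</sub>)/(ρ<sub>NIR</sub> + ρ<sub>RED</sub>),
   plus GNDVI, RENDVI, NLI, OSAVI, GRVI, MSR, SR, NDRER, SPI2 and LCI.
3. **Segmentation** — plant tissue is extracted from the NDVI image by a
   per-image histogram rule: among pixels with NDVI > 0.1, keep the top
   92% of the value distribution, then the largest connected component
   (`segment_plant()`).
4. **Morphology** — twelve binary shape descriptors with classic
   `regionprops` semantics (`compute_features()`): Area, ConvexArea,
   Eccentricity, EquivDiameter, EulerNumber, Extent, FilledArea,
   Orientation, MajorAxisLength, MinorAxisLength, Perimeter, Solidity.
5. **Statistics** — per-week one-way ANOVA and Tukey HSD at 99%
   confidence (`weekly_comparisons()`), degree-1/2 growth regressions
   with R² (`fit_growth_regression()`), classical and functional
   boxplots (`summarize_boxplot()`, `functional_boxplot()` with
   modified band depth).

`run_pipeline()` chains stages 1–5 over a JSON session manifest and
writes masks, index rasters, a long-format CSV feature table and a
provenance sidecar. A synthetic module (`generate_scene()`,
`generate_trial()`, `simulate_session()`) produces scenes and trials
with known ground truth, so the whole chain is testable without any
field data. The methods vignette
(`vignettes/multispectral-phenotyping.Rmd`) documents the model choices,
conventions and limitations.

## Worked example

```r
library(phenomspec)

## a synthetic plant scene with known ground truth
sc   <- generate_scene(scene_spec(dim = c(400, 500), center = c(200, 250),
                                  base_radius = 60, noise_sd = 0.01,
                                  seed = 42))
fr   <- align_bands(sc$bands, shift_profile("none"))
mask <- segment_plant(fr)
mask
#> <plant_mask> 400 x 500 px, 11202 foreground

compute_features(mask)
#> <morpho_features>
#>   Area             11202
#>   ConvexArea       15656
#>   Eccentricity     0.0592718
#>   EquivDiameter    119.427
#>   ...
#>   Perimeter        628.198
#>   Solidity         0.715508

masked_mean(compute_index(fr, "NDVI"), mask)
#> [1] 0.8064
```

The mask holds 11,202 pixels of the ~11,600-pixel blob (the histogram
rule trims the noisiest 8% of candidate NDVI values; on a noiseless
scene recovery is exact). Eccentricity near 0 and solidity ~0.72 say
"roughly circular, heavily lobed" — exactly the generated shape — and
the mean NDVI of 0.806 matches the generating reflectances
(0.55 − 0.06)/(0.55 + 0.06) ≈ 0.803.

Simulated trials feed the statistics layer:

```r
tab <- generate_trial(trial_spec(models = growth_models()["Area"], seed = 7))
cmp <- weekly_comparisons(tab, "Area", alpha = 0.01)
subset(cmp, week == 7 & group_a == "T0" & group_b == "T3")
#>  week variable group_a group_b mean_diff ...  significant
#>     7     Area      T0      T3    -79464 ...         TRUE
```

By week 7 the control's plant area trails the top fertilizer dose by
~79,000 px and Tukey flags the pair at the 1% level. Refitting the
control's weekly means recovers the generating model
(`f(x) = 10290x + 27080, R² = 0.991` against a true slope of 10070 and
intercept of 26550).

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "phenomspec", package = "phenomspec"))')
Rscript $CLI simulate session --out sess --seed 5
Rscript $CLI run --manifest sess/manifest.json --out results \
        --shift-profile none --keep-fraction 0.92 --min-ndvi 0.1
Rscript $CLI stats --table results/features.csv --out results --alpha 0.01
```

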