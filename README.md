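# camtherm

Microstructural temperature proxies from SEM backscatter images of bivalve
shell hinges.

## The scientific problem

Shells of the long-lived ocean quahog *Arctica islandica* archive past water
temperature in the geometry of their crossed-acicular (CA) microstructure:
needle-shaped biomineral units (BMUs) loosely aligned in two dip directions
(~30–40° off the growth front), interspersed with micrometre-scale,
organics-lined pores elongated parallel to the growth front. The overwhelming
majority of BMUs and pores are tiny and temperature-invariant; only the
**largest** entities carry the temperature signal. Under controlled culturing
at 1–15 °C:

- the size *S* of the largest BMUs rises linearly with temperature *T*
  (`S = α + βT`),
- the size of the largest pores rises **exponentially**
  (`S = a·e^{bT}`, endpoint solve `b = ln(10.13/0.68)/14 ≈ 0.193 °C⁻¹`),
- the **BMU coverage** — the percentage of pixels brighter than the mean gray
  value of the image series, a proxy for the areal fraction of crystalline
  phase — also rises with temperature.

Because the signal lives in the extreme upper tail, the analysis pools the
**15 largest** entities of each temperature group (top-N thresholding),
correlates them with temperature (Spearman rank correlation), and fits
linear/exponential calibration models whose inversion yields temperature
estimates from measured sizes. Group distributions are compared with
two-sample Kolmogorov–Smirnov tests on their empirical CDFs. Laboratory-grown
shell zones are delimited from Mn/Ca transects (LA-ICP-MS spots along the
growth axis): oxygen-rich tank water leaves a Mn/Ca level two orders of
magnitude below the low-oxygen field signal, detected as a single robust
changepoint.

`camtherm` implements the full measurement chain for researchers in
sclerochronology and biomineralization:

| stage | functions |
|---|---|
| synthetic imagery with ground truth | `synthetic_config()`, `generate_microstructure_image()`, `sample_bmu_population()`, `generate_mnca_profile()` |
| image/table I/O | `read_sem_image()`, `write_label_mask()`, `read_particle_table()`, `read_mnca_table()` |
| segmentation | `compute_feature_stack()`, `train_pixel_classifier()`, `predict_mask()`, `binarize_mean_threshold()`, `coverage()` |
| morphometry | `label_components()`, `measure_particles()`, `summarize_specimen()` |
| proxy statistics | `size_ecdf()`, `ks_two_sample()`, `top_n_largest()`, `threshold_sensitivity()`, `spearman_cor()`, `fit_linear()`, `fit_exponential()`, `predict_temperature()` |
| Mn/Ca zoning | `detect_changepoint()`, `zone_summary()` |
| orchestration / CLI | `simulate_temperature_ladder()`, `run_proxy_pipeline()`, `camtherm_cli()` (`inst/cli/camtherm`) |

Because no public SEM image set accompanies the deposited morphometric data,
the package ships a first-class synthetic-image generator that emulates the
CA microstructure (bright anisotropic BMU plateaus with soft rims, dark
elongated pores, topographic gray shading, imaging noise, dirt/scratch
artifacts) with exact per-entity ground truth, so the whole pipeline is
testable end to end.

## Worked example

```r
library(camtherm)

## one synthetic specimen cultured at 9 °C
cfg <- synthetic_config(temperature = 9, seed = 1)
g   <- generate_microstructure_image(cfg)
g$image
#> <sem_image> 320 x 320 px, pixel_area 0.0003 um^2 (30.7 um^2 field), specimen synthetic, T = 9 C

## train a pixel classifier from sparse labels and segment
labels <- labels_from_truth(g$truth, "bmu", n_regions = 15, seed = 2)
clf    <- train_pixel_classifier(g$image, labels, seed = 3)
clf
#> <pixel_classifier> 100 trees, 237 training pixels (entity: 109, background: 128), OOB accuracy 0.998
mask <- predict_mask(clf, g$image)
mask_iou(mask, g$truth$bmu_mask > 0, exclude = g$truth$artifact_mask)
#> [1] 0.998

## measure particles (>2 px, artifacts excluded)
rec <- measure_particles(label_components(mask), cfg$pixel_area,
                         exclusion = g$truth$artifact_mask,
                         specimen_id = "demo", temperature = 9)
summarize_specimen(rec, region_area = prod(cfg$canvas_size) * cfg$pixel_area)
#>   specimen_id   n max_area_um2 region_area_um2   p50    p90   p99 p99.9
#> 1        demo 277        0.736            30.7 0.012 0.0384 0.336 0.736
```

The summary reads: 277 BMUs were measured in a 30.7 µm² field; the median BMU
is 0.012 µm² while the largest is 0.736 µm² — the heavy small-size bulk with
a sparse large tail that makes top-N thresholding necessary.

Calibration on the 15 largest pores of each temperature group of a simulated
six-level ladder, and inverse temperature prediction:

```r
pores <- do.call(rbind, lapply(c(1, 3, 6, 9, 12, 15), function(t) {
  do.call(rbind, lapply(1:3, function(s) {
    p <- sample_pore_population(synthetic_config(temperature = t,
                                                 seed = 100 * t + s))
    p$specimen_id <- sprintf("T%02d-S%d", t, s); p$temperature <- t
    p
  }))
}))
top <- do.call(rbind, lapply(split(pores, pores$temperature),
                             top_n_largest, n = 15))
fit <- fit_exponential(top$temperature, top$area_um2)
fit
#> <calibration_model: exponential> S = 0.01509 exp(0.1724 T) (n = 90)
#>   Spearman r = 0.895 (r^2 = 0.802, p = 1.12e-32); regression r^2 = 0.679
#>   residual sign-runs p = 4.31e-12; negative predictions on [0,16] C: FALSE
predict_temperature(fit, 0.1)
#>   area temperature lower upper extrapolated
#> 1  0.1          11  10.2  11.6        FALSE
```

The fitted pore growth rate (0.172 °C⁻¹) recovers the configured exponential
scaling; a 0.1 µm² top-pore size maps back to 11.0 °C with a ±2 SE interval
of 10.2–11.6 °C. Mn/Ca zoning:

```r
s <- generate_mnca_profile(502.39, 4.26, n_pre = 12, n_post = 8,
                           noise_cv = 0.5, seed = 5, specimen_id = "S01")
detect_changepoint(s)
#> <zone_split> S01: changepoint at spot 13 [ok]; pre 420.5 +/- 261, post 3.491 +/- 1.4 (median +/- 1 IQR)
```

A command-line interface mirrors the pipeline stages
(`simulate`, `segment`, `measure`, `coverage`, `stats`, `calibrate`,
`zones`); see `inst/cli/camtherm`. All stages are deterministic: identical
config and seed give byte-identical outputs.

## Methods

See the methods vignette (`vignettes/microstructure-proxy.Rmd`) for the
generative model, the segmentation feature bank, numerical conventions
(thresholding ties, elongation of degenerate components, top-N tie-breaks)
and known limitations.
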