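---
title: "Quantifying temperature from crossed-acicular shell microstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temperature from crossed-acicular shell microstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtherm)
```

## The measurement problem

SEM backscatter images of H₂O₂-etched hinge-plate surfaces of *Arctica
islandica* encode surface topography as gray value: polished tops of
biomineral units (BMUs) emit strongly (bright), while etched inter-crystalline
depressions and pores emit weakly (dark). Three quantities derived from these
images act as temperature proxies:

1. **largest-BMU size** — the mean area of the 15 largest BMUs of a
   temperature group scales linearly with culturing temperature;
2. **largest-pore size** — the same statistic for pores scales exponentially,
   `S = a·e^{bT}`;
3. **BMU coverage** — the percentage of pixels brighter than the mean gray
   value of the image batch, which rises with temperature.

The distributional structure that motivates the top-15 statistic is extreme:
the bulk of BMU cross-sections is very small (mostly oblique cuts through
needles) and temperature-invariant, so group-level signal is confined to the
upper tail. Conversely, using ever larger subsets dilutes the correlation with
temperature (`threshold_sensitivity()` reproduces this decay).

## The synthetic-image generator

No public image set accompanies the deposited per-entity data, so the package
generates CA-like imagery with exact ground truth. The generative model is the
minimal one consistent with the observed behaviour:

* **BMU sizes** are a two-component mixture: a temperature-invariant
  lognormal bulk (default median 0.012 µm², σ_log = 0.8) and, with
  probability `tail_fraction` (default 0.03), a "large" component with
  lognormal median `bmu_tail_base + bmu_tail_scale_slope · T`
  (default 0.12 + 0.04·T µm², σ_log = 0.25). Only the tail moves with
  temperature, mirroring the empirical ECDFs in which 99.9 % of entities are
  invariant. The spec of the linear scaling gives only a slope; the intercept
  `bmu_tail_base` is needed to place the cold-end tail and is exposed as a
  config field.
* **Orientations** follow the two CA dip directions: modes at ±35° off the
  growth front (image vertical; growth direction horizontal), Gaussian spread
  8°. Elongations are Uniform(2, 4) — needle-shaped cross sections.
* **Pores** arrive as a spatial Poisson process (default 0.7 µm⁻²) with
  lognormal sizes whose scale is multiplied by `e^{bT}`; the default rate
  `b = ln(10.13/0.68)/14 ≈ 0.193 °C⁻¹` is the two-point solve through the
  endpoint means of the published pore calibration. Pore long axes lie within
  a few degrees of the growth front.
* **Rendering**: background 0.35, BMU plateau 0.85 with a 1-px rim at 0.62
  (the gently dipping etched edge), pores 0.10; additive Gaussian noise
  (σ = 0.05); occasional bright scratches and dark dirt blobs recorded in an
  artifact mask. Gray values are quantized onto the 16-bit grid so TIFF
  round-trips are bit-identical. Topography is emulated purely as intensity —
  no 3-D rendering.

Two rasterization decisions matter for testability. Each entity is drawn by
selecting exactly `round(area/pixel_area)` pixels of smallest elliptical
quadratic form, so rendered component areas equal intended areas to the
pixel. Entities are placed by rejection sampling with a 1-px halo, so
components never touch under 8-connectivity and the truth table maps
one-to-one onto mask components. Pores are placed *before* BMUs: they are
rare, and placing them into an already crowded canvas would selectively drop
the largest pores at warm temperatures — truncating exactly the tail that
carries the signal and biasing the recovered exponential rate downward (we
observed 0.08 °C⁻¹ instead of 0.193 °C⁻¹ with the reversed order).

**Problem sizes.** The default canvas is 320 × 320 px at the native pixel
area of 0.0003 µm², i.e. a ~31 µm² analysed region — deliberately far smaller
than the 1,218–47,479 µm² regions of the original study, with entity sizes
scaled down accordingly (top BMUs ~0.2–1 µm² instead of 2–19 µm²). This keeps
a full 6-temperature × 3-specimen ladder, including random-forest
segmentation of all 18 images, at around two minutes on a single CPU.
Consequently the package's synthetic results reproduce the *relationships*
(correlation signs and strengths, exponential-rate recovery, coverage trend),
not the absolute sizes printed for the real shells.

What the generator does **not** emulate: merging/fused BMUs (real CA units
share boundaries; the paper explicitly does not split them), spatially
correlated SEM noise, charging gradients, magnification-dependent resolution,
or within-specimen growth-axis trends. Passing tests therefore demonstrate
correctness of the measurement chain, not field performance on real imagery.

## Segmentation

`compute_feature_stack()` builds the multiscale feature bank standard in
interactive pixel-classification tools: raw intensity plus, at each scale
σ ∈ {0.7, 1.0, 1.6, 3.5, 5.0} px, the Gaussian-smoothed intensity, gradient
magnitude, Laplacian of Gaussian, and the leading eigenvalues of the
structure tensor and Hessian (26 features). Borders are handled by mirror
reflection. `train_pixel_classifier()` fits a 100-tree random forest
(seedable, single-threaded for determinism) on sparsely labelled regions and
refuses fewer than 10 labelled regions per class per image. Classification
is by majority class probability; ties go to background.

The coverage statistic uses a deliberately simpler rule,
`binarize_mean_threshold()`: one global threshold equal to the mean intensity
of the supplied batch (the default; a per-image mode exists because the
source describes both a per-analysis and an all-images averaging set, without
disambiguating). A pixel is white iff strictly greater than the threshold —
ties are black; the source does not state tie handling, so the strict rule is
fixed and documented. Batch-mean thresholding is invariant under affine
rescaling applied jointly to the batch.

When deriving training labels from ground truth (`labels_from_truth()`),
half of the background regions are sampled within 7 px of entity boundaries.
This mimics how users annotate boundary context and proved necessary: with
only far-field background labels the forest assigned a 1-px false-positive
halo around pores (IoU ≈ 0.75 instead of ≈ 0.96).

## Morphometry

`label_components()` labels connected components (8-connectivity by default,
the standard for bright blobs; 4-connectivity available) via a pixel
adjacency graph; labels are assigned in raster order, so runs are
reproducible. `measure_particles()` reports areas in both pixels and µm²,
drops components overlapping the exclusion mask (fractures, dirt, scratches)
and below `min_pixels` — default 3, the strict reading of "larger than two
pixels". Elongation is the major/minor axis ratio of the second-central-
moment equivalent ellipse (point-mass convention), matching "ratio of longest
to shortest axes" semantics while staying stable on small irregular
components; a Feret-caliper mode exists for sensitivity checks. Degenerate
single-file components have a zero minor moment; they are flagged and
assigned elongation = pixel count (a length/width = 1 proxy), a case the
source does not define.

## Proxy statistics

* `size_ecdf()` — right-continuous ECDF with order-statistic quantiles
  (`sorted[⌈p·n⌉]`), matching a sort-and-index definition exactly.
* `ks_two_sample()` — `D = sup|F_a − F_b|` evaluated at every pooled
  observation; the two-sided asymptotic p-value is delegated to
  `stats::ks.test()`. No multiple-testing correction is applied (none is in
  the source analysis).
* `top_n_largest()` — the 15 largest areas pooled across a group's specimens.
  Correlation is computed on the pooled values paired with their group
  temperature (n = 15 × groups); a group-means view is available via the
  calibration input. Boundary ties are broken by (specimen id, entity id) so
  selection is deterministic. Nominal temperatures are used for ranks;
  because Spearman works on ranks, measured group means (1.1, 3.2, …) give
  identical correlations.
* `fit_linear()` / `fit_exponential()` — OLS and Levenberg–Marquardt NLS
  (`minpack.lm`), the latter initialized from the log-linear fit with a
  two-point fallback for non-positive areas and a closed-form shortcut for
  zero-variance inputs. Parameter SEs come from the fit covariance; the ±2 SE
  prediction band uses the delta method. "Non-random residuals" — the stated
  ground for rejecting linear pore models — is operationalized as a
  Wald–Wolfowitz sign-runs test plus a negativity check of predictions over
  0–16 °C. Both Spearman r² and the regression r² are reported separately:
  the published r/r² pairs are consistent with r² of the rank correlation for
  BMUs (0.82² ≈ 0.67) but not for pores (0.92² ≠ 0.77), so the two
  quantities are kept distinct rather than conflated.
* `predict_temperature()` — model inversion with the ±2 SE band propagated by
  root finding; estimates outside the 1–15 °C calibrated range carry an
  extrapolation flag. At the package's scaled-down group sizes (top 15 of
  ~60 pores), leave-one-temperature-out recovery of middle levels holds
  within ±2 °C in the median across seeded ladders; individual levels can
  exceed it through top-15 sampling noise.

## Mn/Ca zoning

Laboratory-grown shell is identified from Mn/Ca transects: tank water is
oxygen-rich, so Mn/Ca collapses from a field median near 500 µmol/mol to a
few µmol/mol. `detect_changepoint()` searches the single split minimizing the
summed absolute deviation from segment medians — a robust L1 binary
segmentation, chosen because the field zone is heavy-tailed (IQR ≈ 377 at
median ≈ 502) and the published summaries are medians. Exactly one
changepoint is modelled (the experiment defines one transition), the split
must be a *decrease* (else flagged `no_lab_zone_signature`), and the index is
invariant to positive rescaling of the series. `zone_summary()` pools spots
across specimens by default (per-specimen averaging available; the source
does not state which was used) and reports median ± one inner quartile range.

## Numerical conventions and degenerate inputs

* Pixel coordinates are 0-free R conventions: (row, col), 1-based, row-major;
  the growth front is the image vertical. Areas are always carried in both
  px and µm².
* All generators are pure functions of (config, seed); the caller's RNG state
  is saved and restored. Per-image seeds of a ladder are derived as
  `(seed·1009 + 101·i + s) mod 2³¹−1`.
* Intensities live in [0, 1]; images are quantized to the 16-bit grid at
  generation, making every CLI stage byte-reproducible (logs echo flags by
  basename and carry no timestamps).
* Overcrowding is checked against the *analytic* expectation of entity pixels
  under the config (error above 60 % of the canvas), so a valid config cannot
  fail stochastically; realized occupancy above 90 % is a hard error.
* Empty masks, empty record sets, constant series and zero-variance
  calibrations all return well-defined flagged results rather than erroring,
  except where a result would be meaningless (empty ECDF, all-pixels-excluded
  coverage).

## Known limitations

* The pixel classifier is trained and evaluated on synthetic imagery whose
  classes are far more separable than real etched surfaces; real use will
  need user-supplied labels and should expect lower IoU.
* Touching/fused BMUs are not split (consistent with the source method); on
  real CA fabric, measured "BMU" components can be multi-unit aggregates.
* The exponential pore model is fitted on the natural scale, so cold-end
  (small-area) lack of fit penalizes inverse predictions below ~3 °C more
  than warm ones.
* Coverage depends on the batch composing the mean threshold; mixing image
  sets with different gray-balance changes the statistic (the per-image mode
  trades comparability for robustness to batch effects).
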