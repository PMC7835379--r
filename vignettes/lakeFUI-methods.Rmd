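---
title: "lakeFUI: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lakeFUI: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeFUI)
```

## The retrieval model

The package turns multiband surface-reflectance composites into per-lake
Forel-Ule Index (FUI) series. The chain rests on three physical
assumptions:

1. **Additive surface contamination.** After product-level atmospheric
   correction, reflectance over water still contains skylight reflection,
   residual aerosol and sun glint. These are treated as spectrally flat
   within a pixel, while the water-leaving signal in the NIR-SWIR is
   essentially zero for non-extreme waters. The per-pixel minimum across
   the NIR-SWIR bands therefore estimates the additive offset, and
   `correct_water_leaving()` subtracts it from every band. The operation
   is translation-invariant — adding a constant to all bands of a pixel
   leaves the corrected visible bands unchanged — which is exactly the
   error structure it is designed to remove.
2. **SWIR land/water contrast.** At 1640 nm water is dark (observed
   values are the surface offset) and land is bright, so the histogram of
   a lake plus its surrounding buffer is bimodal and a per-lake threshold
   can be read off the valley (`find_threshold()`).
3. **Hue carries the water-quality signal.** The corrected R, G, B map
   linearly to CIE tristimulus values, the chromaticity azimuth around
   the white point (1/3, 1/3) gives the hue angle α, and the 21 Forel-Ule
   classes partition the α axis (`fui_lut()`, `classify_fui()`). Because
   chromaticity is brightness-normalised, the classification is invariant
   to scaling of (R, G, B) — the property that makes FUI robust.

### The deviation correction and its reachable range

Broad satellite bands reconstruct a hue angle that is systematically
offset from the true-colour hue. The offset is modelled as a degree-5
polynomial Δ(α/100) applied as `α_corrected = α + Δ` before
classification (`delta_correction()`). Two conventions for the hue angle
circulate in the water-colour literature; both are provided
(`hue_angle()`, anticlockwise from the positive x-axis, decreasing with
FUI; `hue_angle_prime()`, the legacy clockwise convention, increasing
with FUI). For the colour locus they satisfy α + α′ = 270° exactly, which
the shipped table reproduces row by row.

One consequence of applying Δ over the whole circle deserves a note: the
map `α → α + Δ(α)` is not monotone and attains a global **minimum of
about 41.27° near α ≈ 58.4°**. Corrected angles below that floor — the
tabulated angles of classes 17–21 — can therefore never be produced by
the satellite path. Real very-turbid waters saturate at class 16 under
this correction; the classifier's clamp (`α` below the class-21 angle →
21) handles the other end. The calibration range of the polynomial is not
stated in the literature it comes from, so the package applies it over
[0, 360) and documents the floor rather than extrapolating a fix. The
synthetic generator's `modis_bias` inversion refuses classes 17–21 with
an explicit error for the same reason, while the plain true-colour
inverse (`modis_bias = FALSE`) covers all 21 classes and round-trips with
Δ disabled — mirroring the rule that Δ corrects satellite colour, not
true colour (field spectra in `fui_from_spectrum()` default to
`apply_delta = FALSE` likewise).

## Tunable parameters

All constants live in `pipeline_config()`; printed workflow values are
defaults, nothing is hard-coded at call sites.

| parameter | default | units | role |
|---|---|---|---|
| `t0`, `t1` | 0.04, 0.12 | reflectance | 1640 nm threshold search window |
| `bin_width` | 0.002 | reflectance | histogram bin for the valley search |
| `occurrence` | 0.30 | fraction | normal-mask occurrence floor (strict `>`) |
| `coverage` | 0.30 | fraction | monthly observed-pixel floor (strict `>`) |
| `shallow_blue` | 0.06 | reflectance | water-leaving blue ceiling for optically deep water |
| `k_temporal` | 3 | σ | per-pixel monthly outlier window |
| `k_spatial` | 1.5 | σ | lake-mean trimming window |
| `min_months_nonfreezing` | 6 | months/yr | validity rule |
| `min_months_freezing` | 3 | months/yr | validity rule (May–Oct only) |
| `min_area_km2` | 25 | km² | component floor (≥ 100 px at 500 m) |

Histogram **binning is unsmoothed** and the valley is the global minimum
bin inside the window, ties toward the lower reflectance; the original
workflow's binning is unstated, so both are configurable. If no bin falls
in the window or the counts are monotone across it (no valley — the
bimodality prerequisite fails), the midpoint (t0 + t1)/2 is used with a
warning flag rather than an error, since a single cloudy composite should
not abort a 19-year record.

The **shallow-water blue threshold** replaces a manual
visual-interpretation step that cannot be automated; 0.06 in
water-leaving blue cleanly separates the generator's deep water from its
planted bright-bottom rims and is deliberately conservative. The test is
applied to the *corrected* blue: on raw reflectance the additive offset
would push dark clear lakes over any fixed ceiling.

Thresholding for extraction, by contrast, runs on the **raw** 1640 nm
band: the water-leaving correction zeroes the NIR-SWIR minimum over both
land and water and would destroy the very contrast the histogram method
needs. (This is easy to get wrong; an acceptance test guards it.)

## Numerical and procedural decisions

- **Filters are single-pass** with the sample standard deviation (n−1).
  Neither choice is stated in the source workflow; single-pass is the
  literal reading, and with the small monthly samples involved the n−1 vs
  n choice never changes a decision in the worked examples. With fewer
  than 3 values σ is meaningless and nothing is removed; a pass that
  would delete more than half the sample is refused with a warning
  (`temporal_filter()`, `spatial_mean()`).
- **Classification** is nearest tabulated angle with clamping at both
  ends and ties to the lower (bluer) class; with strictly decreasing
  table angles this is identical to interval-midpoint boundaries.
- **White point**: chromaticities within 1e-12 of (1/3, 1/3) have no
  defined hue; scalar paths reject them, the raster path marks the pixel
  invalid.
- **Negative reflectance** after correction is clamped to 0 and flagged
  per pixel (`$clamped`); pixels with all-zero visible bands afterwards
  are marked `$invalid_rgb` and excluded from retrieval. Whether the
  original processing clamped or discarded is unstated; clamping keeps
  the pixel count stable and is flagged for audit.
- **Occurrence denominator**: a pixel's occurrence frequency is counted
  over the composites on which it is *observable* (no cloud, shadow,
  ice, mixed or noise flag), not over all composites — an unobservable
  date carries no information about water presence.
- **Connectivity and morphology**: 8-connectivity for components (keeps
  diagonal channels connected), 3×3 structuring element for the 1-pixel
  (= 500 m at native resolution) shoreline erosion and for buffer
  dilation; the buffer grows ring by ring until the expanded area first
  reaches 1.5× the component area.
- **Validity**: a lake failing its months rule in *any* year is dropped
  entirely (the stricter of the two possible readings); per-year
  dropping is available behind `drop_lake_on_any_bad_year = FALSE`.
- **Gap filling** interpolates interior gaps only, on the month index;
  leading/trailing gaps stay missing, and for freezing lakes no
  interpolation crosses a winter break. The operation is idempotent and
  never alters observed values.
- **Trends**: OLS slope of yearly FUI on calendar year with a two-sided
  t-test (p < 0.01 is the significance convention carried into the
  output tables); Mann-Kendall with Sen's slope is available as
  `method = "mann-kendall"` for series with outliers or ties.
- **Matchups**: nearest pixel by planar grid distance, nearest date
  within an inclusive ±1 day window, time ties to the earlier date;
  every dropped site carries a logged reason. MRD is asymmetric (the
  measured series is the reference); RMSE is symmetric.
- **Band resampling** of field spectra uses rectangular windows over the
  nominal band ranges (red 620–670, green 545–565, blue 459–479 nm);
  true sensor spectral response functions are not modelled.

## The synthetic world

`scene_spec()` / `generate_scene()` / `generate_series()` state an
explicit observation model: per band, observed = intrinsic water-leaving
reflectance + flat additive offset + Gaussian noise. The intrinsic
NIR-SWIR of water is zero, so the observed water SWIR *is* the offset
(glint floor `water_swir_level` = 0.02 plus sky/aerosol
`residual_level` = 0.01 — the residual magnitude after product-level
correction is not characterised anywhere, so it is an invented,
configurable default). Land sits at 0.20 ± 0.03 at 1640 nm (truncated at
0.05 above the residual): the heterogeneity spreads a land tail into the
threshold window, which is what makes the histogram genuinely bimodal
rather than two spikes. Gaussian band noise defaults to 0.001
(sub-percent radiometric noise after compositing). Clouds are random
bright discs grown until the requested cover fraction is reached — the
pipeline reads QA flags, not cloud optics, so blob realism is
irrelevant. One integer seed drives one RNG stream per scene (stream
order: land heterogeneity, cloud placement, band noise), derived
deterministically from the master seed and the date index; identical
spec and seed give bitwise-identical rasters.

Lake trajectories follow a seasonal sinusoid (amplitude default 2
classes, peaking in boreal summer) around a per-lake base class, rounded
to classes. **Planted outliers** perturb a contiguous random patch of
10–30 % of a lake's pixels in a composite (probability `outlier_rate`
per lake-date), emulating undetected thin cloud or glint. The patch
design is deliberate: a whole-lake outlier composite would be
mathematically unremovable by a single-pass μ±3σ filter over the ≤ 4
composites of a month (for n values the largest |z| is (n−1)/√n < 3
whenever n ≤ 10), whereas a minority spatial patch is exactly what the
μ±1.5σ spatial trim absorbs — the noise class that filter exists for.
Freezing lakes carry QA ice flags on all November–April scenes.

What the generator does **not** emulate: radiative-transfer coupling
between bands, bidirectional effects, mixed land/water shoreline optics
beyond the planted shallow rims, spatially correlated noise, sensor
degradation, or the sinusoidal tiling and HDF packaging of the real
product. A green test suite therefore establishes that the *chain of
rules* is implemented exactly as stated and recovers planted truth under
the stated error structure — it does not re-validate the published
accuracy against field campaigns (MRD 6.5 %, RMSE 1.09 over 151
matchups), the 1049-lake inventory, or cross-mission correlations, all
of which need external archives.

## Formats

No GDAL-backed raster package is assumed: scenes travel as plain-text
ESRI ASCII grids (one per band, plus an integer QA grid) with a JSON
sidecar for date, band names, CRS label and pixel size, and all tables
are CSV in the published dataset's column layout (`lake_info.csv`,
`raw_monthly_FUI.csv`, `filled_monthly_FUI.csv`, `yearly_FUI.csv`).
Within R, a scene is a named list of matrices with an affine transform —
adapters to GeoTIFF are a thin seam away if a GDAL binding is available.

## Known limitations

- Classes 17–21 are unreachable through the Δ-corrected satellite path
  (see above); very turbid waters saturate at 16.
- The α range over which Δ was fitted is unknown; outside the colour
  locus the classifier clamp is the only guard.
- The printed look-up table's angles disagree with recomputation from
  its own 4-decimal chromaticities by up to ~0.03°, implying
  higher-precision source coordinates; the table is shipped verbatim and
  all tolerances budget for the rounding.
- Freezing status is an external per-lake input (the temperature
  climatology used originally is out of scope).
- Geographic coordinates are whatever the affine transform provides; no
  reprojection is performed.
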