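---
title: "Methods: phenology-based wheat mapping and climate-driver analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenology-based wheat mapping and climate-driver analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatscape)
```

## The analysis chain

wheatscape implements a complete agro-meteorological analysis chain for a
winter-wheat province observed through two instruments: a seasonal LAI
(leaf-area-index) raster time series, and daily records from a small
network of meteorological stations. The chain is

1. **Wheat mapping** — classify each pixel's seasonal LAI curve as winter
   wheat or not, using the crop's double-feature phenology;
2. **Accuracy assessment** — compare extracted planting area against
   yearbook (reference) area by relative error;
3. **Frequency mapping** — count per-pixel wheat presence over equal
   multi-year intervals and difference consecutive intervals;
4. **Seasonal met aggregation** — accumulate daily temperature,
   precipitation and sunshine over the growing window;
5. **Trend and mutation testing** — Mann–Kendall `Z` plus sequential
   UF/UB curves whose in-band crossings date abrupt changes;
6. **Yield decomposition** — Hodrick–Prescott split of annual area/yield
   into a smooth trend and a high-frequency climatic component;
7. **Driver ranking** — Pearson correlations of the met factors against
   area, yield and their annual differences, with significance stars.

Because the real satellite, station and yearbook inputs of such a study
are not redistributable, the package ships a synthetic-data module that
emulates the study system with known ground truth; every downstream stage
is exercised and tested against that truth.

## The growing window

Winter wheat is sown in early October and harvested in late May. All
seasonal quantities use the window from ordinal day 273 of the year
before harvest through ordinal day 145 of the harvest year, inclusive:
238 days when the sowing year is a common year, 239 when it is leap.
Ordinal days are interpreted in each calendar year's own calendar, which
makes the window boundary wobble by one calendar day around leap
Februaries; we accept this wobble rather than fixing calendar dates,
since the day-of-year definition is the natural one for satellite
composites. Accumulated temperature is the plain sum of daily means
`(tmax + tmin)/2` over the window with no base-temperature cutoff: the
emulated system's provincial mean of roughly 3311 °C over 238 days
implies a 13.9 °C/day window mean, consistent with an uncut sum, and no
base is part of the definition. The provincial value is the unweighted
mean over stations; spatial interpolation is out of scope.

## Wheat classification

A winter-wheat LAI curve has two distinctive features inside the growing
window: an autumn rise to a low over-wintering plateau, and a spring
green-up peak followed by senescence to near zero before harvest. The
classifier reduces each pixel's curve to features and applies four
clauses. Numerical choices, fixed once and exposed in
`phenology_windows()`:

* smoothing: 3-composite moving average, partial windows at the edges;
* peak: argmax of the smoothed curve, first index on ties;
* inflections: strict sign changes of the second difference of the
  smoothed curve (a zero run is not a sign change, so flat curves have no
  inflections);
* clauses: peak index inside the spring window, at least one inflection
  inside the autumn window, final smoothed LAI at most `lai_sow_max`
  (default 0.5) of the peak, and peak at least `lai_max_threshold`
  (default 2.0 LAI).

The three climatic-period windows default to composites 1–5, 8–13 and
14–16 of a 16-composite season and scale proportionally for other
composite counts; they are configuration, not code, because their exact
boundaries are crop- and region-specific. Interior nodata composites are
linearly interpolated; pixels with boundary nodata or fewer than six
valid composites are skipped (`NA`), not errors. Grids entering mask
algebra must share shape and geotransform exactly; this package never
resamples.

No geospatial raster stack is required: cubes and masks are in-memory
arrays/matrices carrying a GDAL-style affine transform attribute, and
round-trip to plain CSV with a JSON sidecar (`write_lai_cube()`,
`write_mask()`), keeping all artifacts text.

## Mann–Kendall trend and mutation testing

`mk_statistic()` computes `S`, the sum of `sign(x_i − x_j)` over ordered
pairs `j < i`, with the tie-corrected variance
`Var(S) = [n(n−1)(2n+5) − Σ t(t−1)(2t+5)]/18` and the continuity
correction on `Z`. The sequential curves follow the progressive/
retrograde construction: `UF_i` standardizes the cumulative
exceedance count with mean `i(i−1)/4` and variance `i(i−1)(2i+5)/72`;
`UB` is the same statistic on the reversed series, negated and
re-reversed. No tie correction is applied inside the sequential
statistic — ties are rare in continuous meteorological aggregates. A
mutation year is a strict sign change of `UF − UB` whose interpolated
crossing lies within `±z_crit` (default 1.96, i.e. two-sided 5%); a run
of exact zeros flanked by opposite signs reports the run's first year,
and `UF ≡ UB` reports nothing, which keeps flat series quiet. No
prewhitening or Sen's slope is provided.

## HP decomposition

`hp_filter()` minimizes `Σ(x_t − τ_t)² + λ Σ(Δ²τ_t)²` and is solved
exactly via the Woodbury form `τ = x − D'(DD' + I/λ)⁻¹ Dx`, which is
well-conditioned at both λ extremes (λ→0 gives `τ = x`; λ→∞ gives the
least-squares line). The default `λ = 100` is the common annual-data
convention (6.25 is a documented stricter alternative); the series here
have `n ≤ 40`, so the exact dense solve is essentially free. The
climatic component is defined as the residual `x − τ`, making
conservation exact by construction. The package treats the HP trend as
*the* trend-yield concept; no spline or loess alternative is offered.

## Driver correlations

`build_corr_table()` produces the 3 × 4 grid (factors T, P, h against
area, Δarea, yield, Δyield) of Pearson `r`, two-sided t-test p-values
and star marks (`*` p < 0.05, `**` p < 0.01; no multiple-testing
correction, matching the reporting convention the grid emulates).
Annual differences are paired with the met *levels* of the later year by
default (`diff_met = TRUE` switches to differenced factors). For
strongly trending series, level correlations mostly measure shared
trends: with a 4× yield growth over 40 years, the trend dominates the
variance and every trending factor correlates near ±1 regardless of its
climatic role. The `detrended = TRUE` option therefore correlates the HP
climatic components of both sides; that is the view used for the
sign-recovery experiments below, while raw levels remain the default
output.

## The synthetic study system

The generator (`synth_config()` defaults) emulates a 40-season
(1980–2019) province with LAI mapping over 2000–2019:

* **LAI cubes** — 50 × 50 pixels at 250 m (6.25 ha), 16 composites per
  season; 70% cropland of which 40% carries wheat each season, re-drawn
  per season so planting frequency varies. Wheat curves are sums of two
  logistic pulses (autumn plateau ~0.9 LAI, spring peak ~4 LAI, near
  zero at harvest) with ±0.5-composite timing and ±0.5-LAI amplitude
  jitter; non-wheat cropland is either flat low cover or a late-rising
  summer crop; background is 0.15 LAI. Additive Gaussian noise (sd 0.15
  by default) is clamped at zero, slightly truncating the noise at low
  LAI — a real LAI product is similarly bounded. The generator does not
  model spatial autocorrelation, mixed pixels, atmospheric artifacts or
  real GLASS spectra, so the near-perfect recovery in the tests bounds
  algorithmic correctness, not real-world accuracy.
* **Meteorology** — 7 stations; daily mean temperature is a sinusoid
  (base 17.71 °C, amplitude 11 °C, peak at day 205) calibrated so the
  40-year window mean sits at the emulated system's ~3311 °C, plus a
  drift of 116.91 °C of accumulated temperature per decade, a per-season
  anomaly, and 1.5 °C daily noise; a fixed 10 °C diurnal range gives
  tmax/tmin. Precipitation uses a summer-peaked wet-day probability with
  gamma amounts (window totals ~380 mm); sunshine a seasonal cycle with
  a −20 h/decade drift, reduced by 3 h on wet days (~1400 h window
  totals). Per-season anomalies of (T, P, h) are drawn from a trivariate
  normal with correlations (T,P) = 0.5, (T,h) = −0.2, (P,h) = −0.45 —
  monsoon covariation: warm seasons tend wetter, wet seasons duller.
  This covariation matters: with mutually independent factors the sum of
  squared factor–yield correlations is bounded by 1, and no weight
  choice can make all three signs *and* the full |r| ranking recoverable
  95% of the time at n = 40.
* **Area/yield series** — quadratic rising trends (area 3927 → ~5480
  k ha; yield 9.0 → ~34 Mt) plus a climatic component
  `w_T z(T) + w_P z(P) + w_h z(h)` built from standardized met
  *anomalies* (linear drift removed before z-scoring, so the climatic
  component is trend-free), with default weights (1, 0.55, −0.3) and
  white noise at 0.25 of the climatic scale (120 k ha, 1.2 Mt).
  Injected change points are mean shifts (default 2 climatic scales),
  carried in the stored trend so components sum exactly to the series.
  A one-off design simulation (100 replicates) of the detrended yield
  grid under these defaults gave mean correlations (0.88, 0.76, −0.48)
  and a 98% joint sign-and-ranking recovery rate; the constants were
  frozen on that basis before the test suite was finalized.

Every generator is driven by deterministic sub-seeds derived from the
single configuration seed, so identical configurations reproduce
bit-identical outputs.

## Problem sizes in the test suite

The suite exercises: the exhaustive S/Z oracle over all 3-letter series
of lengths 4–8 (9,801 series); MK calibration with 2,000 null and 500
trend replicates at n = 40 (the power experiment uses a 1-sd-per-decade
trend, comparable to the emulated system's own drift-to-noise ratio of
~2 sd/decade); change-point recovery over 200 replicates; 50 × 50-pixel
extraction cubes; and 200 generator replicates for the sign/ranking
recovery rate. These sizes keep every Monte-Carlo estimate's sampling
error well inside the margins asserted, while the full suite runs in a
few minutes on one core.

## Known limitations

* The classifier is a fixed-rule system; it does not learn thresholds
  and will misclassify crops whose phenology mimics wheat's double
  feature inside the configured windows.
* Station aggregation assumes an unweighted station mean is an adequate
  provincial summary; there is no gridding, elevation correction or
  homogenization.
* The UF/UB crossing rule can report multiple mutation years on noisy
  series; the curves themselves should always be inspected.
* Correlation tables are descriptive: no autocorrelation correction is
  applied to p-values, and annual series of length ~40 give wide
  sampling bands on r (~±0.15 at |r| ≈ 0.5).
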