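---
title: "Methods: Köppen-Geiger map building in koppenmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Köppen-Geiger map building in koppenmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koppenmap)
```

## The classification model

The Köppen-Geiger system assigns one of 30 classes to a location from its
twelve monthly mean air temperatures (°C) and precipitation totals
(mm/month). All decisions flow from a small set of derived indices
(`climate_indices()`): the annual mean temperature MAT and total MAP, the
coldest- and warmest-month temperatures `T_cold` / `T_hot`, the number of
months above 10 °C, and seasonal precipitation extremes taken over the
*summer* and *winter half-years* — whichever of the fixed blocks
April–September and October–March is warmer, respectively colder, on
average (`season_split()`).

The arid class is defined through the aridity threshold

\[
P_\mathrm{threshold} =
\begin{cases}
2\,\mathrm{MAT} & \text{if } >70\% \text{ of MAP falls in winter},\\
2\,\mathrm{MAT}+28 & \text{if } >70\% \text{ of MAP falls in summer},\\
2\,\mathrm{MAT}+14 & \text{otherwise},
\end{cases}
\]

and a cell is arid (B) when `MAP < 10 * P_threshold`, desert (BW) when
`MAP < 5 * P_threshold`, steppe (BS) otherwise, hot (h) when `MAT >= 18`.
B takes precedence over every other class, because the tropical, temperate,
cold and polar definitions are mutually exclusive among themselves but each
can intersect the arid criterion. After B, the majors split on
`T_hot <= 10` (E: tundra if `T_hot > 0`, frost otherwise), `T_cold >= 18`
(A: rainforest if the driest month has ≥60 mm, else monsoon if
`P_dry >= 100 - MAP/25`, else savannah), `0 < T_cold < 18` (C) and
`T_cold <= 0` (D). Within C and D the dry-summer criterion
(`P_sdry < 40` and `P_sdry < P_wwet/3`) and dry-winter criterion
(`P_wdry < P_swet/10`) are made mutually exclusive: when both hold, s is
assigned if strictly more precipitation falls in winter than in summer, and
w otherwise. Third letters are thermal: a (`T_hot >= 22`), b (not a, ≥4
months above 10 °C), d within D (not a/b and `T_cold < -38`), and c for the
rest.

### Decisions where the rule set under-determines behavior

These corners are not fixed by the classification table; the package pins
them down as follows, and the test suite asserts each one:

- **Half-year tie.** If the two fixed half-years have equal mean
  temperature, summer is April–September. This only happens for seasonally
  flat profiles, where every seasonal sub-criterion is inert anyway.
- **Zero annual precipitation.** The winter fraction is undefined; the
  "otherwise" threshold branch (`2·MAT + 14`) is used. Any finite choice
  classifies such cells identically whenever `P_threshold > 0`.
- **Negative thresholds.** For MAT below −7 °C the threshold can be ≤0; the
  formulas are applied literally, so such cells are never arid. No special
  case is introduced.
- **s/w conflict ties.** Equal winter and summer totals resolve to w — the
  s condition requires strictly more winter precipitation.
- **70 % boundaries are strict**: exactly 70 % takes the middle branch.
- **Class codes.** The code↔symbol bijection is fixed in table-row order
  (Af=1, Am=2, Aw=3, BWh=4 … ET=29, EF=30), with colors adapted from the
  Peel scheme; `write_legend()` emits it as `code symbol R G B` lines.
- **C-class third letter.** The table's c criterion (1–3 months above
  10 °C) is implemented as "not a, not b"; within C the two are equivalent,
  since `T_hot > 10` guarantees at least one such month.

The production classifier is fully vectorized over cells. An independently
written, deliberately literal scalar evaluator lives in the test suite and
must agree with it on 10⁵ random climatologies spanning −60…40 °C and
0…1000 mm/month; boundary semantics (18 °C, 0 °C, the 5× and 10× threshold
multiples, the 25 mm monsoon line, 22 °C, the 4-month rule, −38 °C) are
additionally pinned by exact-value tests.

## Temporal homogenization and the anomaly method

Climatological datasets rarely share a temporal span, and climate-model
output cannot be used directly at fine resolution. Both problems are solved
by the same delta-change machinery: per month, compute the change between
two period climatologies of a coarse reference series — additive offsets
for temperature, multiplicative factors for precipitation — resample the
twelve change grids to the fine grid with bilinear interpolation, and apply
them to a fine baseline (`homogenize()`, `future_ensemble()`). Multiplying
precipitation (rather than adding) preserves non-negativity and respects
the skewed distribution of monthly totals; superimposing modeled
*anomalies* on an observed baseline removes the mean bias of each model.

Numerical choices:

- **Factor guard.** Ratios use `target / max(source, epsilon)` with
  `epsilon = 0.01` mm/month and are capped at 10. Over realistic fields the
  cap never binds (change factors stay well below ~5, since near-zero
  baseline months are rare and arid regions tend to dry rather than wet);
  it only guards degenerate synthetic baselines.
- **Interpolation convention.** Bilinear weights are anchored at cell
  centers. Fine centers beyond the outermost coarse centers are clamped to
  the edge value (no extrapolation); when the coarse grid spans 360° of
  longitude the interpolation wraps across the antimeridian. Masked coarse
  neighbors are dropped and the remaining weights renormalized, so
  coastlines do not erode one cell inland; a cell with four masked
  neighbors stays masked.
- **Identity invariants.** `change_field(X, X)` is exactly zero / one, and
  homogenizing a dataset to its own span leaves classifications unchanged;
  both are asserted in tests, as is exactness of the interpolator on fields
  linear in longitude and latitude.

## Ensembles and confidence

Each (temperature, precipitation) dataset pair — or each climate model —
yields one classification; the final map takes the per-cell modal class and
the confidence level `100 × modal frequency / n`. Decisions:

- The denominator is the full ensemble size `n` even where some members are
  nodata (matching the fixed 12 and 32 denominators of the published maps);
  cells valid in no member are nodata.
- Modal ties break toward the lowest class code: deterministic and
  order-independent (permutation invariance is tested).
- Confidence is kept as a floating percentage; files round to the nearest
  integer for the 8-bit format, and display truncates to one decimal
  (`format_confidence()`, so 8/12 prints as 66.6).
- Models missing a variable or period are skipped with a warning and
  counted, not imputed.

## Rasters

Maps are single-band uint8 GeoTIFFs on the WGS84 graticule: codes 1–30 with
nodata 0, grid-cell (area) registration. The package carries its own
minimal GeoTIFF codec (uncompressed, little-endian, ModelPixelScale /
ModelTiepoint / GeoKey directory, GDAL-style nodata tag; uint8 for maps,
float32 for climatology stacks); a test verifies the files against an
independent TIFF reader. Cell sizes are constructed from exact rationals
(1/120°, 1/12°, 1/2°) so geotransforms round-trip bit-for-bit — 0.0083° is
the rounded display of 1/120°. Class maps are coarsened by majority
resampling (block mode, nodata ignored, ties to the lowest code);
confidence maps by block-mean aggregation, the aggregation reading of
"bilinear averaging" — a true bilinear interpolator is not an aggregator
and would undersample the block.

## Station validation

Daily station records are aggregated to monthly values only when at least
25 daily values are present in the month (temperature by the mean;
precipitation as mean daily amount × days in month, which treats months
with 25–30 present days consistently). Calendar-month climatologies are
formed only from at least 10 yearly values, and a station failing any month
of either variable is rejected — a reported outcome with a reason, not an
error. Both thresholds are inclusive exactly as stated (24 days fails, 25
passes; 9 years fails, 10 passes) and are boundary-tested. Stations are
compared against the class of the grid cell containing their coordinates —
no interpolation, since classes are categorical; a point exactly on a cell
edge belongs to the south-east cell. Duplicate station ids keep their first
occurrence. Accuracy is the percentage of evaluated stations (those inside
the extent and on classified cells) whose map class matches their own
climatology's class, and the confidence split reports mean map confidence
separately for correct and misclassified stations.

## The synthetic world

`synth_world()` builds a seeded analytic planet. Temperature: an
equator-to-pole decline of the annual mean (28 °C at the equator, dropping
44 °C toward the poles with exponent 1.5), a seasonal amplitude envelope
that is small in the tropics, peaks near 65° and declines toward the poles,
a longitudinal continentality factor (±45 %) that amplifies the seasonal
cycle and cools high-latitude continental interiors, a hemisphere phase
flip (warmest month July vs January), and an optional elevation field with
a 6.5 °C/km lapse rate. Precipitation: zonal bands with prescribed
regimes — uniform wet tropics, summer-peaked monsoon/savannah belt, an arid
belt whose wetness cycles with longitude (desert vs steppe sectors), a
winter-wet Mediterranean belt, uniform temperate midlatitudes, a
summer-peaked subpolar belt and dry polar caps. Seasonal profiles are
raised-cosine curves; the winter-wet band concentrates ~78 % of its total
in winter, safely beyond the 70 % seasonality branch.

The defaults (0.5° global grid, 360×720) exercise all five major classes
and 22 of the 30 sub-types, with the majors in the correct poleward order
along any meridian — both asserted by enumeration. Noise, when requested,
is additive white for temperature and multiplicative lognormal for
precipitation, and every generator is a pure function of (recipe, seed);
the ground-truth map is always computed from the noise-free fields.

Coarse time series (`synth_coarse_series()`) aggregate the world to a 2°
grid (the same coarse-to-fine chain as a 0.5°-reference / 1-km-map
pipeline, scaled down by the same ratio class) and add a linear per-decade
drift anchored at the first year of the period, plus optional interannual
noise. Model pairs (`synth_model_pair()`) shift the future period by a
uniform warming and scale precipitation by a constant — so the anomaly
pipeline can be checked for exact identity (zero warming, unit scale) and
for parameter recovery (the recovered offsets/factors must match the
injected values within noise tolerance). Station records
(`synth_stations()`) sample cells of the world, optionally with daily
noise, random gaps and engineered QC failures (every January capped at 24
daily values).

What the synthetic world deliberately lacks: topographic relief (unless an
elevation field is supplied), weather and interannual variability beyond
the prescribed drift/noise, spatially correlated model biases, oceans, and
observation error structure. Passing the synthetic end-to-end tests
therefore demonstrates the correctness of the *pipeline* — the classifier,
the delta-change algebra, the voting, the file formats and the QC rules —
not the skill of any real-world map; the published headline accuracies
(80 % against 22,078 stations, confidence means of 92.6 %/77.4 %) depend on
the real climatic archives and station databases, which this package
does not ship.

## Problem sizes and reproducibility

The study-condition runs use the 0.5° world (259,200 cells), a 3×4 = 12
member present ensemble, 32 synthetic models over 1980–2016 / 2071–2100 on
a 2° model grid, 10⁵ random climatologies for the oracle comparison and
40-station validation panels; the full pipeline completes in a few minutes
on one CPU. All randomness is seeded, ensemble operations are
order-invariant, and repeated runs produce byte-identical rasters and
manifests (`run_present()` / `run_future()` write no timestamps for that
reason).
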