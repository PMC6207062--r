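# koppenmap

Köppen-Geiger climate classification maps with ensemble confidence, in R.

The Köppen-Geiger system partitions climates into 5 major classes and 30
sub-types — tropical (A), arid (B), temperate (C), cold (D) and polar (E) —
from thresholds and seasonality of monthly air temperature (°C) and
precipitation (mm/month). Because vegetation integrates climate, the classes
track biome boundaries, which makes the maps a standard input for species
and vegetation distribution modeling and for climate-change impact
assessment. `koppenmap` implements the full map-production pipeline around
that classifier:

- **Classifier** (`koppen_classify()`, `koppen_codes()`, `classify_stack()`)
  — the 30-class rule set on monthly climatologies. The arid class B takes
  precedence via the aridity threshold
  `P_threshold = 2·MAT (+28 | +14)` selected by whether >70 % of
  precipitation falls in the winter or summer half-year; the remaining cells
  split on `T_hot ≤ 10` (E), `T_cold ≥ 18` (A), `0 < T_cold < 18` (C) and
  `T_cold ≤ 0` (D), with seasonal (s/w/f) and thermal (a/b/c/d, h/k, T/F)
  sub-criteria. The dry-summer and dry-winter sub-types are mutually
  exclusive: when both criteria hold, s is assigned where winter receives
  more precipitation than summer, w otherwise.
- **Delta-change machinery** (`period_climatology()`, `change_field()`,
  `bilinear_to_grid()`, `apply_change()`, `homogenize()`) — per-month
  additive temperature offsets and multiplicative precipitation factors
  between two periods of a coarse reference series, resampled to the fine
  grid by cell-center bilinear interpolation. This both homogenizes
  climatologies with mismatched temporal coverage to a common baseline
  (1980–2016) and drives the anomaly method for future (2071–2100)
  projections, where modeled anomalies are superimposed on the observed
  baseline to cancel model mean biases.
- **Ensemble mapping** (`present_ensemble()`, `future_ensemble()`,
  `majority_vote()`, `reference_climatology()`) — one map per
  temperature×precipitation dataset pair (or per climate model), combined by
  per-cell majority vote; the confidence level is
  `100 × (modal-class frequency) / (ensemble size)`.
- **Raster I/O** (`write_class_map()`, `read_class_map()`,
  `upscale_majority()`, `upscale_mean()`, `standard_grid()`,
  `write_legend()`) — single-band uint8 GeoTIFF on the WGS84 graticule
  (codes 1–30, nodata 0), the three published global grids (1/120°, 1/12°,
  1/2°), majority resampling for classes and block-mean aggregation for
  confidence, and the plain-text class legend.
- **Station validation** (`monthly_means()`, `station_climatology()`,
  `classification_accuracy()`, `confidence_split()`) — station monthly
  climatologies under strict completeness rules (months need ≥25 daily
  values; calendar months need ≥10 yearly values, else the station is
  rejected), classification accuracy against station-derived classes, and
  the mean-confidence split between correctly and incorrectly classified
  stations.
- **Synthetic fixtures** (`synth_world()`, `synth_coarse_series()`,
  `synth_model_pair()`, `synth_stations()`) — a seeded analytic planet with
  the latitudinal climate ladder, coarse drifting time series, climate-model
  pairs with injected warming/precipitation scaling, and gappy daily station
  records, so the entire pipeline is testable offline.

A thin command-line front end lives in `exec/koppenmap`
(`legend`, `classify`, `info`, `upscale`, `synth-world`, `present`,
`validate`).

## Worked example

```r
library(koppenmap)

# a Mediterranean-type station climatology
temp   <- c(8, 9, 11, 13, 17, 21, 24, 24, 21, 16, 12, 9)    # degC
precip <- c(80, 70, 60, 50, 30, 10, 5, 10, 40, 70, 90, 85)  # mm/month

koppen_classify(temp, precip)$symbol
#> [1] "Csa"

ind <- climate_indices(temp, precip)
c(MAP = ind$MAP, winter_frac = round(ind$winter_frac, 3),
  P_threshold = round(ind$P_threshold, 2))
#>         MAP winter_frac P_threshold
#>     600.000       0.758       30.83
```

600 mm falls per year, 75.8 % of it in the winter half-year (>70 %, so the
aridity threshold is `2·MAT = 30.83`); the annual total is well above
`10 × 30.83`, so the cell is not arid, the coldest month (8 °C) makes it
temperate, the dry summer month (5 mm < 40 and < 90/3) gives `s`, and the
24 °C warmest month (≥22) the `a`: **Csa**, hot-summer Mediterranean.

A full synthetic pipeline run:

```r
w <- synth_world()                                      # 0.5 degree planet
res <- run_present(list(w$temp), list(w$precip), "out") # classify + vote + GeoTIFFs
mean(res$classes$codes == w$truth$codes)                # 1 (noise-free world)

daily <- synth_stations(w, n = 40, years = c(2001, 2012), seed = 1)
rep <- run_validate(res$classes, res$confidence, daily, "out")
rep$accuracy
#> [1] 100
```

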