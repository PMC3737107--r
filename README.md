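# nestsurvey

Chimpanzees and other great apes are rarely seen during surveys, but the
nests they build each night are countable from line transects. `nestsurvey`
implements the full inference chain that turns perpendicular nest-detection
distances into animal density and population size, for field ecologists and
analysts running or re-analysing ape nest surveys:

* **Detection functions** — conventional distance sampling with uniform and
  half-normal keys plus cosine adjustment series, fitted by constrained
  maximum likelihood (non-negative, non-increasing detection curves),
  selected by AIC, checked by chi-square, Kolmogorov–Smirnov and
  Cramér–von Mises goodness of fit.
* **Standing-Crop Nest Counts (SCNC)** — one visit, all nests, the
  line-transect estimator

  D̂\_nests = n · f̂(0) / (2L)

  with `n` the detected nests, `f̂(0)` the detection-distance density at
  zero, and `L` the total transect length.
* **Marked Nest Counts (MNC)** — repeated visits, only newly built nests,
  the strip-transect estimator

  D̂\_builders = n / (2 s L t p̂)

  with strip half-width `s` read off the shoulder of the detection
  function, `t` the days between first and last visit, and `p̂` the nest
  production rate (nests/builder/day).
* **Nest decay rate** — back-calculated from the steady-state identity
  D̂\_nests = D̂\_builders · p̂ · r̂, i.e. r̂ = D̂\_nests / (D̂\_builders · p̂),
  with the CV propagated by the delta method (squared CVs add).
* **Habitat weighting, bootstrap, abundance** — habitat-area-weighted
  average densities, transect-level nonparametric bootstrap CIs
  (999 resamples by default), and scaling to population size.
* **Spatial randomization test** — are nests farther from roads, rivers
  and settlements than uniformly random locations inside an 84 m transect
  buffer would be? Monte Carlo test (1000 relocations by default) on mean
  nearest straight-line distances, in planar projected coordinates.
* **A survey simulator** — a seeded birth–death nest process with
  distance-dependent detection over a systematic transect grid and habitat
  mosaic, so every stage can be validated against known ground truth.

## Worked example

Simulate a two-year survey (11 transects × 3 km, biweekly visits, true
builder density 0.5/km², production 1.143 nests/builder/day, mean nest
lifetime 294 days) and run the whole chain:

```r
library(nestsurvey)

cfg <- simulation_config(seed = 42)
sv  <- simulate_survey(cfg)

scnc <- run_scnc(sv$observations, sv$layout, year = 2010, w = 42,
                 stratify = "pooled", keys = "half-normal",
                 max_adjustments = 1, B = 999, seed = 42)
scnc$global
#> scnc (global): 154.77 nests/km^2 [95% CI 135.91-174.80], %CV = 6.50

mnc <- run_mnc_decay(sv$observations, sv$layout, year = 2010, w = 44,
                     stratify = "pooled", keys = "half-normal",
                     max_adjustments = 1, B = 999, seed = 42,
                     nest_density = scnc$global)
mnc$global
#> mnc (global): 0.53 builders/km^2 [95% CI 0.32-0.80], %CV = 23.64
mnc$decay
#> Nest decay rate: 253.3 days (%CV = 24.77)

population_size(builders_from_nests(scnc$global, mnc$decay), 622.7)
#> Population size: 333 animals (95% CI 292.3-375.9) over 622.7 km^2
```

The standing crop of 155 nests/km² is the accumulation of ~0.5 builders/km²
each producing 1.143 nests/day that persist ~294 days (0.5 × 1.143 × 294 =
168 at stationarity); the MNC stream recovers the builder density directly
(truth 0.5), and the back-calculated decay rate lands near the generating
294-day lifetime. On a single survey these estimates carry substantial
sampling noise — the recovery *distribution* is what the acceptance script
quantifies.

Nest placement versus landscape features (here nests were generated
preferentially in dense forest, away from the synthetic road/river/
settlement layers):

```r
cfg2 <- simulation_config(
  builder_density = c(DF = 1.6, OF = 0.6, SAV = 0.15, OTH = 0.15),
  feature_bias = 1.5, seed = 42)
sv2 <- simulate_survey(cfg2)
rr  <- run_randomization(sv2$observations[sv2$observations$visit == 1,
                                          c("x_utm", "y_utm")],
                         sv2$layers, sv2$transect_geoms, R = 1000, seed = 42)
rr$report[, c("layer", "observed_mean_km", "z", "p_one_sided")]
#>        layer observed_mean_km        z p_one_sided
#> 1       road         10.65534 7.396138           1
#> 2      river         12.55062 7.493908           1
#> 3 settlement         12.55464 6.635260           1
```

`z` is the observed mean nearest-feature distance in null-standard-deviation
units; the one-sided p is the fraction of null means *below* the observed
mean (so values near 1 mean nests sit farther from features than chance;
the two-sided companion is also reported).

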