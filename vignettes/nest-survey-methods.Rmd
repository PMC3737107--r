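---
title: "Methods: nest count surveys, decay-rate back-calculation and spatial randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nest count surveys, decay-rate back-calculation and spatial randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

Great apes build a fresh sleeping nest most nights, and nests persist for
months. A survey that walks line transects and records the perpendicular
distance to every visible nest can therefore estimate animal density
without ever seeing an animal — provided three quantities are linked
correctly: how detectability decays with distance, how fast nests are
produced, and how long they last. `nestsurvey` implements that chain, plus
a randomization test for whether nests avoid human-disturbance features,
and a simulator that generates complete surveys with known ground truth.

Throughout the package, transect lengths are kilometres, perpendicular
distances and detection scales metres, and densities per square kilometre;
the single m–km conversion for the density estimators lives in one internal
utility so the 10^6 area factor cannot scatter.

# Detection functions

The detection curve is the conventional key-plus-series form
$g(y) = \mathrm{key}(y)\,[1 + \sum_{j=1}^{m} a_j \cos(j\pi y / w)]$ with a
uniform or half-normal key, truncation distance $w$, and cosine order
$m \le 3$. The fitted density of detection distances is $f(y) = g(y)/\mu$
with $\mu = \int_0^w g$, and $f(0)$ — the density at distance zero — is
the quantity the SCNC estimator consumes ($1/f(0)$ is the effective strip
half-width).

**Assumptions.** Nests on the line are always detected ($g(0)$ maximal),
distances are measured without error, and the detection curve has a
"shoulder": it is non-negative and non-increasing on $[0, w]$. The shape
constraint is enforced on a 512-point grid; parameter vectors with $g < 0$
or increments above $10^{-6}$ are rejected.

**Fitting.** The truncated likelihood $\prod_i f(y_i)$ is maximized with
bounded quasi-Newton (`L-BFGS-B`) from five deterministic jittered starts
(no RNG, so fits never perturb the caller's seed), with a convergence
tolerance of $10^{-8}$ on the log-likelihood and 64-node Gauss–Legendre
quadrature for $\mu$. Two numerical details matter near the constraint
boundary (e.g. a uniform key with $a_1 \to 1$, where $g(w) \to 0$):

* the shape penalty used during the search is deliberately *soft*
  (weight $100n$ on squared violations) — a heavy penalty builds a
  numerical cliff that breaks the line search;
* each start is also optimized without any penalty, and infeasible optima
  are pulled back along the ray of their adjustment vector onto the
  feasibility boundary by bisection, so boundary maxima are attained
  exactly. An oracle test checks that returned likelihoods dominate dense
  parameter grids.

Truncation is either a fixed $w$ or a discard fraction (5% is the usual
omnibus choice); discarded records are tallied, and `w = Inf` is the
identity. Model selection is by AIC with ties broken toward fewer
parameters; the adjustment order search is forward stepwise (terms added
while the AIC improves), and the AIC gap to the runner-up is reported.
Models with cosine terms require $n \ge 5(1+m)$ observations; bare keys
are fittable from small samples.

**Goodness of fit.** Chi-square on equal-width bins (default
$\min(10, \lfloor n/5\rfloor)$, expected counts from the fitted CDF,
$df = \mathrm{bins} - 1 - \mathrm{npar}$, with an error rather than a
silent merge when an expected count drops below 1), Kolmogorov–Smirnov via
the fitted CDF, and Cramér–von Mises with the Stephens small-sample
modification referred to the asymptotic distribution (the classical
Bessel-K series). All three p-values are the usual "naive" ones that
ignore parameter estimation — the convention of standard distance-sampling
software — which makes them mildly conservative; no parametric-bootstrap
p is computed by default.

**Strip half-width.** The MNC estimator needs the distance $s$ over which
detection is effectively certain. We define $s$ as the largest
$x \in [0, w]$ with $g(x)/g(0) \ge \tau$, default $\tau = 0.9$,
configurable: the field definition ("the extent of the shoulder") has no
operational rule, and 0.9 keeps the within-strip detection loss below
about 5% for half-normal-like curves while not collapsing $s$ to zero.
For a half-normal key $s = \sigma\sqrt{2\ln(1/\tau)}$ in closed form, which
the implementation reproduces numerically.

# Density estimators

**SCNC** (standing crop, single visit): $\hat D = n\hat f(0)/(2L)$, in
nests/km². Detection functions may be fitted per habitat (default) or
pooled; the field description of per-habitat detection is ambiguous
between the two, so both are supported — per-habitat respects the strong
dependence of visibility on canopy, pooled is the robust small-sample
choice.

**MNC** (marked nests, repeat visits): $\hat D = n/(2sLt\hat p)$ in
builders/km², where $n$ counts only nests newly built since the previous
visit, within the strip. $L$ is the one-pass transect length — the
estimator already divides by the elapsed days $t$, so cumulative
multi-visit effort would double-count time. The method assumes no new nest
disappears between visits; with biweekly visits and ~294-day lifetimes the
violation rate is about 14/294 ≈ 5%, which biases MNC slightly downward
(the simulator reproduces this deliberately).

**Rates.** The steady-state identity $D_{nests} = D_{builders}\,p\,r$
links the two streams. Solving for $r$ back-calculates the nest decay rate
(mean lifetime, days) from a year with both estimates; inverting it
converts later SCNC nest densities to builder densities. CVs of products
and quotients combine by the delta method, $\sqrt{\sum CV_i^2}$. By
reporting convention the SCNC builder density inherits the nest-density CV
and relative CI unchanged ($r$ and $p$ treated as constants — the
convention evident in published tables where builder and nest CVs match);
full propagation is available behind `propagate = TRUE`. Display rounding
follows field practice: densities 2 d.p., decay 1 d.p., populations whole
animals (unrounded values are retained).

**Production rate.** No site-specific estimate is generally available;
the default is the long-term Taï National Park value, 1.143
nests/builder/day (%CV 3.51), explicit and overridable.

**Habitat weighting.** Global density is the habitat-area-weighted average
$\sum A_h D_h / \sum A_h$. Habitat areas are an explicit input: published
global densities of this kind often rest on GIS habitat areas that are not
released with the tables, and transect composition shares generally do not
reproduce them, so the package refuses to guess. When no areas are given the pipelines fall
back to per-habitat effort shares (the self-weighting property of a
systematic design).

**Bootstrap.** Uncertainty comes from a nonparametric bootstrap that
resamples whole transects — the replicate unit of the design — with
replacement (999 resamples by default), returning the percentile 95%
interval and $CV = sd/mean$ of the bootstrap distribution. Resamples where
the estimator fails are dropped; more than 20% failures is an error.
Detection refitting per resample is available (`refit_detection = TRUE`)
but off by default: holding $\hat f(0)$ fixed is far cheaper at $B = 999$
and only slightly anti-conservative, since the encounter-rate component
dominates the variance in these designs. Two caveats are worth stating
plainly:

* with very few resampling units the percentile interval undercovers: at
  the 11-transect survey size, measured coverage of a nominal 95% interval
  on Poisson counts is around 90%. The package's coverage validation
  therefore runs at 30 units (measured ≈ 94%), where the percentile
  method's asymptotics apply, and interval widths at 11 transects should
  be read as slightly optimistic;
* replicate experiments must not seed each dataset with consecutive
  integers — adjacent Mersenne–Twister streams correlate enough in their
  first draws to distort coverage estimates by a couple of percent. All
  seeded package functions (`bootstrap_ci`, the simulator, the
  randomization test) take one seed and derive internal streams from it;
  the tests and the acceptance script draw replicate sub-seeds from a
  single master stream.

# Spatial randomization test

Whether nests avoid roads, rivers and settlements is tested by comparing
the observed mean nearest straight-line distance from nest locations to a
feature layer against the same statistic for uniformly random locations
inside the surveyed region — the union of 84 m half-width buffers around
the transects (84 m being the maximum distance at which a nest was
recorded). Coordinates must be planar metres (e.g. UTM); the package does
no reprojection, and inputs that look like lon/lat degrees are rejected.
Geometry is computed directly: exact point-to-segment distances, polygon
interiors at distance zero by ray casting, rejection sampling from the
bounding box for uniform points, and a deterministic 512×512 grid estimate
of the buffer area. End caps are flat by default (the band of points whose
perpendicular foot lies on the line) and configurable to round; the choice
is cosmetic for long thin transect buffers.

Duplicate nest coordinates are collapsed to unique locations before
testing (several nests in one tree share a GPS reading), mirroring the
"independent nest locations" convention. With $R$ randomizations (default
1000) the test reports $Z = (\bar d_{obs} - \bar d_{null})/sd_{null}$ and
a one-sided p defined — following the convention of counting how often the
random-location mean falls short of the observed one — as the fraction
of null means *below* the observed mean. Note the consequence: strong
avoidance of a feature yields $p \approx 1$ under this definition, not
$p \approx 0$, and published tables mixing $Z$ signs with "p < 0.001" are
internally ambiguous about which tail was counted. The package implements
the definition literally and always reports the two-sided companion, so
no guess about intent is baked in. Under its own null the one-sided p is
uniform, which the calibration test verifies (rejection rate at 0.05 held
within 5% ± 4% over 200 seeded experiments). Kruskal–Wallis comparisons of
distances across habitats are a thin pass-through to `stats::kruskal.test`.

# The survey simulator

The simulator generates what the estimators assume, plus the distortions a
real survey would add:

* **Design** — 11 transects of 3 km on a 5 × 6 km lattice (one per cell,
  row-major), visited 4 times in year one and 5 in year two at 14-day
  intervals; 33 km of one-pass effort.
* **Habitat mosaic** — transects are partitioned into 250 m segments with
  habitat drawn from the configured proportions (defaults: savannah
  0.4681, dense forest 0.2628, open forest 0.0997, other cover 0.1694).
  An optional `feature_bias` tilts low-canopy habitat toward the synthetic
  road/river/settlement layers (placed along the western edge) while
  preserving overall proportions in expectation.
* **Nest dynamics** — births are a Poisson process with intensity
  $D_h \times p$ per km² per day inside a band of half-width `w_band`
  (default 60 m) around each segment; lifetimes are exponential with mean
  294 days. Decay in the *estimators* is a single mean lifetime; the
  exponential is purely the generating mechanism, so recovery targets the
  mean, not the shape. A burn-in of five mean lifetimes precedes the first
  visit: the standing crop then sits within $1-e^{-5}$ (≈ 0.7%) of
  stationarity, comfortably inside the ±3% steady-state check (a
  three-lifetime burn-in, a plausible-looking default, leaves a 5%
  deficit that the check would flag).
* **Detection** — a nest alive at a visit is seen with probability
  $\exp(-x^2/2\sigma_h^2)$, with habitat-specific scales (defaults 12 m
  dense forest to 22 m savannah: visibility grows as canopy opens). First
  visits emit the standing crop (`is_new = 0`); later visits emit only
  nests born since the previous visit (`is_new = 1`), never re-emitting
  marked nests. Nests born and decayed within an interval, or missed
  within the strip, are lost — the realistic downward biases of MNC.
* **Reproducibility** — a single mandatory seed drives landscape, dynamics
  and detection through derived internal streams; identical configuration
  and seed give identical surveys.

What the simulator does **not** emulate: habitat-dependent decay or
production, clustered (party) nesting, observer heterogeneity, and
distance measurement error. Passing recovery tests therefore demonstrate
the correctness of the estimation chain under its own assumptions — not
robustness to these real-data complications.

# Validation sizes and expected behaviour

The test suite and `scripts/acceptance.R` run, at sizes chosen to balance
Monte Carlo error against runtime on a single CPU:

* steady-state identity: 200 simulated surveys at the reference regime
  (0.5 builders/km² × 1.143 × 294 d = 168.0 nests/km²), mean standing
  density within ±3%;
* end-to-end recovery: 100 surveys through MNC → decay → SCNC; median
  decay within ±15% of 294 d and median builder density within ±20% of
  0.5/km². The chain is expected to sit a few percent off-centre: the
  strip criterion $\tau = 0.9$ concedes up to ~5% of within-strip
  detections and ~2% of new nests decay before they are counted, so MNC
  runs slightly low and the decay rate correspondingly high;
* detection oracle: fitted likelihoods dominate 200-point parameter grids
  on samples of up to 50 distances; fitted densities integrate to 1
  within $10^{-6}$;
* randomization calibration: 200 experiments with nests drawn from the
  null, $R = 199$;
* bootstrap coverage: 500 Poisson surveys of 30 transects, $B = 999$.

# Known limitations

Hazard-rate keys, Hermite adjustments, covariate detection functions and
cluster detection are out of scope, as are analytic (delta-method)
variances of $\hat f(0)$, density-surface models, raster distance
surfaces, and reprojection. Decay is a scalar mean lifetime, not a
survival curve or a nest-state Markov model. GOF p-values ignore parameter
estimation. Percentile bootstrap intervals at ~10 resampling units
undercover by several percent. The effective area that converts densities
into population sizes must be supplied by the user; published
density/population pairs are the only guide when the GIS areas behind a
study were not released.
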