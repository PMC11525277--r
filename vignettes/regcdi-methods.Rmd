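---
title: "Entropy-weighted combined drought monitoring with regcdi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weighted combined drought monitoring with regcdi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Agricultural drought is the joint outcome of depleted soil moisture, thermal
stress and a stressed canopy; no single remotely sensed indicator captures
all three. **regcdi** builds a *regional combined drought index* (RegCDI): at
every grid pixel, a set of drought indicators is normalized to $[0,1]$,
oriented so that *low values mean drought*, and combined as a convex
combination

$$\mathrm{RegCDI}_j \;=\; \sum_{i=1}^{m} W_i\, r_{ij},$$

where $r_{ij}$ is the normalized value of indicator $i$ in month $j$ and the
weights $W_i$ come from Shannon's entropy method. For each pixel and
indicator, the monthly series is turned into a frequency distribution
$f_{ij} = r_{ij} / \sum_j r_{ij}$, its normalized entropy is

$$H_i = -\frac{1}{\ln n} \sum_{j=1}^{n} f_{ij} \ln f_{ij},
  \qquad 0 \ln 0 := 0,$$

and the weight of each of the $m$ indicators is

$$W_i = \frac{1 - H_i}{m - \sum_{i=1}^m H_i}.$$

A nearly uniform series ($H_i \to 1$) carries little discriminating
information and receives little weight; a series with concentrated lows and
highs receives more. Weights are computed per pixel over the full monthly
record — not per season — so the spatial pattern of the weights is itself a
product (`autoplot()` on an `entropy_weights` object maps it). When all $m$
entropies equal 1 the formula is $0/0$; the package falls back to equal
weights with a warning, which is the natural limit (no indicator is more
informative than another).

The default indicator triple is SMCI (surface soil moisture), TCI (land
surface temperature, inverted) and SIWSI-1 (shortwave-infrared water stress),
covering the soil-moisture, thermal and canopy-water axes. The stack is
generic in $m \ge 2$; `select_indicators()` reproduces the selection rule
(per indicator type, the candidate with the strongest mean correlation
against district yield and standardized yield).

## Candidate indicators and their conventions

All indicator operations act on a `grid_series` — a long tibble of
`(year, month, row, col, value)` with `NA` as the missing-data mask — and
fail loudly on any shape or timestamp mismatch rather than broadcasting.

* **NDWI** $=(\mathrm{NIR}-\mathrm{SWIR})/(\mathrm{NIR}+\mathrm{SWIR})$,
  **NDVI** $=(\mathrm{NIR}-\mathrm{red})/(\mathrm{NIR}+\mathrm{red})$,
  **SIWSI** $=(\rho_{\mathrm{SWIR}}-\rho_2)/(\rho_{\mathrm{SWIR}}+\rho_2)$
  (variant 1 uses the 1628–1652 nm channel, variant 2 the 1230–1250 nm
  channel). A zero denominator masks the cell; it is never silently zero.
* **VCI** $=100\,(\mathrm{NDVI}-\mathrm{NDVI}_{\min})/(\mathrm{NDVI}_{\max}-\mathrm{NDVI}_{\min})$,
  **TCI** $=(\mathrm{LST}_{\max}-\mathrm{LST})/(\mathrm{LST}_{\max}-\mathrm{LST}_{\min})$,
  **SMCI** $=(\mathrm{SSM}-\mathrm{SSM}_{\min})/(\mathrm{SSM}_{\max}-\mathrm{SSM}_{\min})$.
  The climatological envelope is computed **per calendar month across all
  study years** (so "maximum NDVI" is the multi-year maximum for that
  month), the standard convention for condition indices; a whole-series mode
  is available via `grid_climatology(by_month = FALSE)`. Values outside the
  envelope are clipped by default (`clip = FALSE` retains them); a flat
  envelope masks the cell.
* **SMDI**: the soil-water departure $SD_i$ is scaled by the dry-side range
  when $SW_i \le MSW_i$ and the wet-side range otherwise, and accumulates as
  $SMDI_i = 0.5\,SMDI_{i-1} + SD_i/50$ with $SMDI_0 = 0$ (neutral start; the
  0.5 memory makes any initialization decay within about six months). At
  $SW = MSW$ both branches give 0. With $|SD| \le 1$ the recursion is bounded
  by $\pm (1/50)/(1-0.5) = \pm 0.04$ — a forced consequence of the printed
  constants 0.5 and 50 that the tests check to $10^{-6}$ after 25 steps.
  After a masked month the recursion re-initializes from 0 rather than
  carrying state across a data gap.
* **SWDI** $=(\theta - \theta_{FC})/\theta_{AWC}$. Field capacity and
  available water capacity are user inputs; when unavailable,
  `estimate_soil_parameters()` uses the per-pixel 95th percentile of
  $\theta$ for $\theta_{FC}$ and the 95th–5th percentile range for
  $\theta_{AWC}$, flagged as an approximation.
* **SPI-k**: rolling $k$-month precipitation sums, a zero-inflated gamma
  $H(x)=q+(1-q)G(x)$ fitted per pixel and calendar month, then the standard
  normal quantile. The gamma fit uses Thom's closed-form approximate-ML
  estimator (the convention of the SPI literature); a test cross-checks it
  against full ML. At least 15 years are required (configurable); an
  all-zero or (near-)constant accumulation cell is masked with a warning,
  never silently imputed. Because precipitation is nonnegative, rolling-sum
  floating-point residue below $10^{-9}$ is snapped to an exact zero before
  the zero-probability $q$ is estimated.

## Normalization and orientation

`normalize_indicator()` rescales each pixel's series to $[0,1]$ by its own
min–max over the full study period — the same window the weights use. SIWSI
*increases* with stress while SMCI/TCI increase with wetness; combining them
untransformed would let constituents cancel. The package therefore flips
stress-positive indicators ($r \mapsto 1-r$, `invert = TRUE`, applied to
`siwsi1` by default in `regcdi_pipeline()`) so that low RegCDI uniformly
means drought. This orientation step is a deliberate design choice and can
be disabled per indicator. A pixel with a constant series has no range and
is masked.

## Classification

Two schemes map RegCDI to the six USDM-style categories
(D4 exceptional < D3 extreme < D2 severe < D1 moderate < D0 dry < wet):

* **fixed** (default): D4 $\le 0.02$ < D3 $\le 0.05$ < D2 $\le 0.10$ <
  D1 $\le 0.20$ < D0 $\le 0.30$ < wet. Intervals are lower-exclusive,
  upper-inclusive with D4 $=[0, 0.02]$; the printed "a to $\le$ b" style
  fixes upper inclusion and the lower-exclusive side is chosen for
  consistency at shared boundaries, making the six classes an exact
  partition of $[0,1]$.
* **percentile**: the same cuts (2/5/10/20/30) applied to each pixel's own
  empirical CDF — the USDM percentile convention, appropriate when severity
  ranges are site-specific. Note a consequence used below: per pixel, the
  percentile scheme assigns (up to ties) the same *number* of months to each
  category everywhere, so percentile-based counts cannot discriminate
  between pixels; spatial hotspot contrasts use fixed-range counts.

Both modes are exposed because the category table can be read either way;
fixed-range is the default.

## Run theory, hotspots and thresholds

`extract_runs()` decomposes each pixel's series into maximal runs of months
with index strictly below a threshold $\tau$; a month exactly at $\tau$ is
not in drought, and masked months terminate runs (a gap never bridges two
events). Each run is an event with duration (months) and severity (sum of
index values in the run — *lower* sums per month mean worse drought, and the
hotspot severity layer keeps that orientation). The published defaults are
$\tau = 0.12$ for 0.25° grids and $0.17$ for 1° grids; `threshold = "auto"`
recomputes the underlying rule — the mean over pixels of each pixel's
severe-drought (D2) boundary, i.e. its 10th-percentile index value.
`hotspot_stack()` assembles mean annual severity and duration (event sums
divided by the number of study years; masked where a pixel has no events),
total D1–D4 months, D2–D4 months, propensity, and per-season propensities.
D0 ("abnormally dry") is deliberately excluded from all drought counts.

## Validation and early warning

District yields are standardized per district, $z_i = (x_i-\mu)/\sigma$,
with the sample ($n-1$) standard deviation (configurable to population); a
district with fewer than three usable years or zero spread is flagged and
excluded. A yield drought year is $z < 0$. Seasonal severity is the minimum
index over the season's months (maximum drought severity) or the value at a
critical crop-growth-stage month (default August, mid-Kharif, configurable —
no single month is canonical). `correlation_map()` correlates each pixel's
yearly severity with its district's yield or $z$ series.

`confusion()` tallies binary TP/TN/FP/FN (drought positive) or a $k \times k$
class table. Accuracy is $100\,(TP+TN)/\mathrm{total}$ (trace/total for
multi-class); the Matthews correlation is the Pearson correlation of the two
0/1 label vectors, with the convention MCC $=0$ (flagged) when a denominator
factor vanishes. For lagged early warning, the index is binarized by the run
threshold while predictor indicators are binarized by their own percentile
drought classes (D1–D4, the lowest 20% of each pixel's distribution) —
putting predictors with different native scales on a common footing — and
all pixels and months are pooled into one confusion matrix per lead time,
matching the single accuracy/MCC reported per lag and resolution.

## The synthetic scene generator

`generate_scene()` produces the full input set — LST, surface soil moisture,
precipitation, four reflectance bands, a district zone map, a district-year
yield table — as a deterministic function of a `scene_config()`. It emulates
the statistical structure the framework assumes:

* deterministic seasonal cycles: an LST sinusoid peaking pre-monsoon and a
  Jun–Sep monsoon precipitation pulse (gamma-distributed monthly totals,
  monsoon-season mean 280 mm/month);
* AR(1) Gaussian anomalies (lag-1 correlation 0.5) on every field;
* localized multi-month drought episodes: inside an episode, soil moisture
  and precipitation are depressed and LST elevated immediately, while the
  canopy stress signature (NIR down, SWIR and red up, clipped to $[0,1]$)
  follows after a configurable lead (default 1 month) — soil-moisture
  deficit leads the vegetation response;
* yields coupled to the growing season: district-year yield
  $= 1500 - 600 \cdot (\text{mean Kharif episode intensity}) + N(0, 80)$
  kg/ha.

The default configuration fixes the study conditions once: a 5 × 6 grid
(between the 18-pixel 1° and 197-pixel 0.25° scenes of the motivating study,
at desk scale) over 2001–2019, tiled into 30 districts, with one 5–6-month
episode of intensity 0.7–0.8 roughly every third year (regional drought
frequency of about once in three years), alternating between a western and
an eastern subregion. `truth_report()` returns the imposed episode
pixel-months (overlaps merged at maximum intensity) for recovery
experiments.

What the generator does **not** emulate: radiative-transfer realism, spatial
correlation of the anomaly fields beyond the shared seasonal cycles, mixed
land cover, observation/retrieval error structure, or any particular
region's actual climatology. Passing recovery tests therefore show that the
pipeline recovers the structures it assumes — imposed hotspots, a 1-month
soil-moisture lead, a negative yield–drought coupling — not that it would
perform identically on satellite archives.

## Numerical choices and problem sizes

* Masked cells are `NA` throughout; every arithmetic step propagates them,
  and a pixel-month with any masked constituent is masked in RegCDI.
* Entropy/weight identities are exact to $10^{-12}$ against a brute-force
  direct-formula oracle in the tests.
* Percentile ranks use the empirical CDF (ties share the maximum rank).
* The test suite runs the full pipeline on the default 30-pixel, 19-year
  scene and on 3 × 3-pixel, 8-year scenes for unit fixtures; the recovery
  experiments use 10 replicate seeds of the default scene. These sizes are
  the package's chosen desk-scale study conditions.
* Selection tie-breaks: equal mean correlations break by the
  standardized-yield correlation, then lexicographically, with a message.

## Known limitations

* Inputs must be pre-co-registered; the package performs no reprojection or
  resampling between resolutions (resolution is metadata only).
* Monthly time step only; the original weekly SMDI formulation is out of
  scope, as are VHI/VTCI/DSI-style composites and PCA/copula combination
  schemes.
* The NetCDF dialect needs the optional `ncdf4` package; the plain-text CSV
  dialect is always available and is the format the test suite exercises.
* Confusion-matrix validation against yield inherits the coarseness of
  district statistics: a pixel is paired with exactly one district via the
  zone map, and sub-district heterogeneity is invisible.
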