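---
title: "Methods: background-climate controls on the spatial variance of spring phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: background-climate controls on the spatial variance of spring phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Spring leaf unfolding (LU) in temperate deciduous trees is classically
described by thermal-time models: leaves unfold on the first day $d$ on which
the accumulated forcing

$$\mathrm{GDD}_d = \sum_{t_0}^{d} \max(\bar T_d - T_{th},\, 0)$$

reaches a heat requirement $\mathrm{GDD_{req}}$, with daily mean temperature
$\bar T_d$, threshold $T_{th} = 5\,^\circ\mathrm{C}$ and accumulation start
$t_0 = $ 1 January. Chilling is summarised by NCD, the number of days between
1 November and the LU date with $0 \le \bar T \le 5\,^\circ\mathrm{C}$.

These metrics describe *temporal* (year-to-year) variation well. The question
this package addresses is *spatial*: across a network of sites, do long-term
background conditions — temperature, short- and longwave radiation,
precipitation, soil moisture, day length, aridity — shape the site-to-site
variation of median LU and of the heat requirement itself? If the heat
requirement of buds is adapted to local background climate, then
$\mathrm{GDD_{req}}$ is not a constant to be plugged into regional models but
a quantity with its own biogeography.

`phenospace` implements the full analysis chain: phenometrics (GDD series,
heat requirement, chilling days), per-site long-term climate normals, and a
four-step statistical engine — collinearity screen, elastic-net predictor
selection, stepwise variance-inflation-factor (VIF) reduction, and spatially
correlated generalized least squares (GLS) with AIC structure selection —
summarised as an $R^2$ decomposition of predictor importance. Because real
pan-European observation archives cannot be redistributed, the package ships
a synthetic site-network generator whose LU observations are produced by the
thermal-time rule with a *known*, covariate-dependent heat requirement, so
every stage can be validated against ground truth.

## Phenometrics and filters

* The heat requirement of an observation is the cumulative GDD on the LU day;
  the per-site summary is the median of *per-year* requirements (not the
  requirement at the median LU).
* A day exactly at the 5 °C threshold contributes nothing to forcing
  (the max(· , 0) form is applied literally); the chilling band 0–5 °C is
  closed at both ends; all date windows include both endpoints and the LU
  day itself.
* Filters: LU observations outside days 80–152 are treated as responses to
  extreme events and dropped; sites are retained only with more than 5
  remaining years. Even-count medians use the midpoint convention.
* Missing days inside a required window are an error, never silently
  gap-filled. Chilling days are reported missing for a spring whose
  preceding November–December is not covered.

## Climate normals

Two windows summarise background climate: the growing season, fixed at days
of year 180–250 (inclusive; the peak of plant activity, constant across sites
so that site comparisons are unbiased by unknown growing-season length), and
the preseason. "Three months before LU" is interpreted as a fixed 90-day
window ending the day before the site's long-term *median* LU, computed on
real calendar dates (the window may reach into the previous year). A fixed
window length keeps the predictor comparable across sites; anchoring at the
long-term median rather than each year's LU reflects that the analysis
concerns long-term normals. Temperature, radiation and soil moisture are
averaged within windows; precipitation is summed per window and the totals
averaged across years.

Years whose window value falls outside median ± 2 × IQR of the across-year
distribution are excluded as extreme; the rule is deliberately analogous to
the LU outlier filter, is inactive below 3 years, and is applied per
variable. Grid temperature is corrected to site elevation with a constant
lapse rate of 6.4 °C km⁻¹.

Day length is computed from the standard solar-declination/hour-angle
formulae with Spencer's Fourier declination; the default horizon is the
astronomical one (centre of the solar disc, no refraction); passing
`horizon = -0.833` reproduces the common refraction-plus-solar-radius
convention. Polar day and night clamp to 24 and 0 h.

The aridity index $\alpha_E$ is the ratio of actual to potential
evapotranspiration over the growing season, averaged across years. It is
computed by a deliberately simple Priestley–Taylor supply/demand water
balance: daily PET $= 1.26\, s/(s+\gamma)\, R_n$ (converted to mm/day) with a
net-radiation proxy $R_n = (1-0.17)\,SW + LW_\downarrow - 0.98\,\sigma T_K^4$
clamped at zero; daily AET limited by a single-layer soil bucket (capacity
150 mm, supply rate 25.2 mm/day at a full bucket, overflow runs off). The
index is bounded in [0, 1], monotone in precipitation, and swappable behind
the `alpha_e()` interface; it makes no claim to reproduce any particular
land-surface scheme. Sites with long-term $\alpha_E < 0.9$ are classed
drought-prone.

## The statistical engine

1. **Collinearity screen.** Pairwise Pearson correlations; pairs with
   $|r| \ge 0.7$ are flagged. The screen is diagnostic only — removal
   authority rests with the following stages. The 0.7 default is a
   conventional collinearity alarm level and is configurable.
2. **Elastic-net selection** (`glmnet`): mixing $\alpha = 0.5$, penalty by
   10-fold cross-validation with the one-standard-error rule, folds drawn
   deterministically from the run seed, predictors standardized beforehand.
   These hyperparameters are defaults of convenience, not claims; all are
   arguments.
3. **VIF stepwise reduction.** $VIF_j = 1/(1-R_j^2)$ from regressing
   predictor $j$ on the others. While any VIF exceeds 4, the offender with
   the weakest $|r|$ with the response is removed and VIFs are recomputed;
   removals are logged. Perfect collinearity yields an infinite VIF, not an
   error.
4. **Spatial GLS** (`nlme::gls`, maximum likelihood): residual correlation as
   a function of inter-site distance, with candidate families linear,
   exponential, spherical, Gaussian, rational quadratic and independent, an
   optionally fitted nugget, and AIC selection counting regression
   coefficients, the residual variance and all correlation parameters. Ties
   break towards fewer parameters, then a fixed family order. Correlation
   range initialisation: the median pairwise distance. Non-converging
   candidates are flagged and excluded from selection; if none converge the
   cell errors out and is recorded.

Distances: the semivariogram and the synthetic spatial fields use
great-circle (haversine) kilometres. The `nlme` correlation structures
require planar coordinates, so sites are projected with a local
equirectangular projection before fitting; at the regional extents generated
here (hundreds of km) the two metrics agree to a fraction of a percent.
Duplicate coordinates (possible under bootstrap resampling) are jittered by
0.05–0.2 km because distance-based correlation structures require distinct
locations.

**Relative importance.** The model $R^2$ is decomposed by LMG (Shapley-value
averaging of incremental $R^2$ over all predictor orderings), computed on
*whitened* data: both sides of the regression are premultiplied by the
inverse Cholesky factor of the fitted spatial correlation matrix, so the
decomposition is taken in the metric in which residuals are exchangeable.
Shares are non-negative and sum exactly to the whitened-model $R^2$
(enumeration over subsets; more than 15 predictors is refused). The
reporting convention this follows fixes only that importances sum to 100% of
$R^2$; LMG-on-whitened-data is this package's concrete choice of
decomposition. Confidence intervals
come from a site-resampling bootstrap (percentile 2.5/97.5%, at least 100
replicates) with the selected predictors and structure family held fixed and
parameters re-estimated; degenerate resamples are skipped and counted.

## The synthetic study generator

The generator emulates a PEP-like observation campaign over a European-scale
box (default 4–16°E, 47–53°N, elevations skewed towards lowlands, study
years 1970–2016):

* **Temperature**: sinusoidal annual cycle (mean 11.2 °C at 50°N and sea
  level, half-amplitude 9 °C, peak day 196) + latitude gradient
  (0.55 °C/°lat) + lapse (6.4 °C/km) + a spatially correlated site anomaly +
  a shared annual anomaly + AR(1) daily noise (ρ = 0.7, innovation
  2.2 °C).
* **Shortwave**: daily-mean top-of-atmosphere irradiance × stochastic
  transmissivity (logistic scale, mean 0.55) whose site means are spatially
  correlated and differ between spring and summer — regional
  maritime/continental cloudiness contrasts are what make preseason
  radiation identifiable as a predictor.
* **Longwave**: linear in temperature (250 + 4 T W m⁻²) plus noise.
  **Precipitation**: Bernoulli–gamma with spatially correlated,
  season-specific wetness. **Soil moisture**: monthly single-bucket balance.
* **Mechanism**: each site's true heat requirement is
  $\mathrm{GDD^*_{req}} = 220 + 60\,(0.5\, z_{SWP} - 0.3\, z_{PP}) + \varepsilon$
  °C-days, where $z$ are standardized long-term covariates of the site
  (computed from the generated climate over fixed reference windows) and
  $\varepsilon$ is a Gaussian-process residual (exponential covariance on
  great-circle distances, range 100 km, sd 20 °C-days). Yearly LU is the
  first day cumulative GDD at the *site* elevation reaches the requirement,
  plus integer-rounded observation noise (sd 2 days). Site-years that never
  reach the requirement are emitted missing. Species labels are cosmetic
  replicate groups unless coefficients are overridden.

All spatially correlated fields are drawn from a Gaussian process with
exponential covariance — deliberately one of the GLS candidate families, so
structure-recovery tests have a well-defined truth. All randomness flows
from the scenario seed; identical (scenario, seed) pairs reproduce
byte-identical tables.

### Why these default magnitudes

Two pitfalls constrain the defaults, and both are findings worth recording.

First, *effective spatial replication*: with a correlation range of several
hundred km inside a ~900 × 660 km box, the residual field has only a handful
of independent patches, and any spatially smooth predictor correlates with
it by chance — the non-spatial elastic-net stage then selects decoys
freely. The default range of 100 km leaves of the order of fifty effective
patches, enough for selection to be meaningful while still exercising the
spatial GLS.

Second, *anchor coupling*: because the preseason window is anchored at each
site's median LU, every preseason predictor (TP, SWP, LWP, PP, SMP), day
length at LU and NCD are mechanically coupled to the response — a site with
a higher heat requirement unfolds later, shifting its window into warmer,
brighter days. With a large heat-requirement spread this coupling dominates:
preseason temperature becomes a near-copy of the heat requirement
(correlations above 0.9 arise purely mechanically — notably the same
magnitude that real-data analyses report for this pair, which is exactly the
caveat attached to interpreting that correlation as adaptation). The default
effect scale (60 °C-days per standard deviation) and residual sd
(20 °C-days) keep the LU spread moderate (inter-site LU sd of a few days) so
that the causal covariates remain identifiable next to the coupling. The
consequence for real-data use is a genuine limitation, discussed below.

What the generator does *not* emulate: warming trends, frost damage and
other extreme events, autumn phenology, species-specific mechanisms,
observation-network spatial clustering, elevation-dependent radiation, or
the binary layouts of any real archive. Passing tests therefore demonstrate
internal correctness and recoverability under the stated mechanism — not
that real LU data satisfy that mechanism.

## Validation design

The test suite validates in layers (sizes chosen as the package's own
trade-off between statistical resolution and a comfortable desktop run):

* *Formula oracles*: VIF against the inverse-correlation-matrix diagonal
  (100 random 5-predictor matrices, 1e-10), GDD/LU round trips (1000 random
  series), calendar hand counts for chilling, lapse arithmetic, day length
  against a brute-force hour-angle scan with an independent almanac-style
  solar position (< 0.1 h), the aridity index against a scalar day-by-day
  bucket oracle (< 1e-9).
* *Limiting cases*: independent-structure GLS equals OLS (< 1e-8); an
  exponential structure with vanishing range converges to OLS; the elastic
  net at a near-zero penalty matches least squares.
* *Structure selection*: 50 datasets per regime (n = 300) generated under
  exponential (range 150 km) versus independent residuals; AIC must pick
  the generating regime in at least 80% per regime.
* *End-to-end recovery*: 50 replicates of the default 500-site scenario
  (8 observation years); the pipeline must select SWP and PP with the
  generating signs in at least 90% of replicates, with importance shares
  always non-negative and summing to $R^2$ within 1e-6.
* *Null control*: 25 replicates with all generating slopes zero. Because
  LU-anchored predictors are mechanically coupled to the response (see
  above), false positives are counted over the six fixed-window decoys (TG,
  SWG, LWG, PG, SMG, $\alpha_E$), and a false positive means present in the
  final model with a GLS Wald p < 0.05 — the spatial GLS is the stage that
  controls spurious smooth-decoy effects which the elastic net, by design a
  liberal screen, lets through. Thresholds: mean per-decoy rate ≤ 10%, any
  single decoy ≤ 20%.

`scripts/acceptance.R` reruns the full pipeline once (500 sites, 12
observation years, both responses, all-sites and drought-prone strata) and
writes the headline quantities — model $R^2$ values, the
requirement–preseason-temperature correlation, importance shares of the
generating covariates, variability summaries — to JSON.

## Known limitations

* The anchor-coupling issue is not an artefact of the generator: any real
  analysis that anchors preseason windows at the observed LU and then uses
  preseason predictors for LU or its heat requirement inherits it.
  Importance attributed to preseason temperature or day length should be
  read as partly mechanical.
* The aridity surrogate is a one-bucket Priestley–Taylor balance; absolute
  $\alpha_E$ levels (and therefore the 0.9 drought threshold) shift with
  the assumed capacity, albedo and supply rate.
* Pooled-species runs include no species terms; species are treated as
  replicate networks.
* The LMG decomposition is exponential in the number of predictors and is
  refused above 15 (after selection and VIF reduction, real runs are far
  below this).
* GLS fitting cost grows as the cube of the site count; networks beyond a
  few thousand sites need subsampling or sparse approximations that this
  package does not provide.
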