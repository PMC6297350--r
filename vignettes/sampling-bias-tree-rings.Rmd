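---
title: "Quantifying sampling bias in tree-ring networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sampling bias in tree-ring networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringbias)
library(dplyr)
```

## The problem

Dendroclimatological archives are not random samples of forests. For
decades, field protocols have deliberately selected old trees growing under
marginal conditions — low-elevation range edges, steep rocky slopes with
little water-holding capacity — because such trees carry the strongest
climate signal in their ring widths. A representative forest-inventory
sample, collected on a systematic spatial grid with one or two cores per
plot, sees a very different population: younger trees, moister average
sites, weaker and more heterogeneous climate response.

When a climate–growth model fitted to a targeted archive is used to project
forest growth under warming, the projection applies the climate response of
the most sensitive trees to the whole forest. `ringbias` implements the
full comparison pipeline — simulate (or read), detrend, regress, contrast
locally, aggregate regionally, project — so the size and direction of this
distortion can be measured under controlled, known-truth conditions.

## The data-generating model

The generator produces ring widths as

$$ w_t = \left(a e^{-b\,t} + k\right)\cdot
   \max\!\big(0.05,\; 1 + m\,(\beta_P z_{P,t} + \beta_F z_{F,t} +
   \beta_S z_{S,t})\big)\cdot \varepsilon_t, $$

where $t$ is cambial age, $(a, b, k)$ is the tree's ontogenetic
negative-exponential curve, $m \ge 0$ the micro-site multiplier,
$(\beta_P, \beta_F, \beta_S)$ the slopes on the three standardized seasonal
predictors (cool-season precipitation, prior-fall and current-summer
maximum temperature), and $\varepsilon_t$ lognormal noise. The climate
response is multiplicative on the ontogenetic curve because the analysis
works with ratio indices; the floor at 0.05 keeps widths positive
(`clip_floor = -Inf` disables it for exact-linearity checks). With
`noise_sd = 0` and detrending by the *true* curve, the downstream
regression recovers $m\beta$ to floating-point precision — this exactness
is what makes the generator useful as an oracle.

Three biases distinguish the targeted from the representative draw:

- **age**: targeted trees come from the oldest `age_quantile` (default
  0.25) of the site's age distribution; sensitivity grows with age as
  $1 + \gamma\,\ln(\mathrm{age}/75)$ with $\gamma = 0.3$, so old trees are
  genuinely more responsive, not just older;
- **macro-site**: targeted sites come from the lowest `elev_quantile`
  (default 1/3) of the elevation distribution, and site-level sensitivity
  scales with an aridity score that increases with decreasing elevation,
  decreasing latitude and increasing longitude;
- **micro-site**: the lognormal micro-multiplier (population mean 1,
  `sdlog` 0.2) is shifted up by `micro_bias = 0.4` in the targeted sample.

Representative sampling assigns plots to sites in a gridded round-robin and
cores $1 + \mathrm{Poisson}(0.4)$ trees per plot (mean 1.4, the inventory
average), drawn from the full age distribution.

### Condition choices

Chosen once, as plausible semi-arid Southwest values, and not revisited:

| quantity | default | why |
|---|---|---|
| landscape | 50 sites, 33–37.5° N, −112…−107.5° E | density such that a 100 km radius usually holds ≥ 10 same-species inventory series, so the neighborhood discard rule bites only occasionally |
| cool-season precipitation normal | 160 mm × exp(−0.25 · aridity) | typical cool-season totals; monotone along the gradient |
| monthly anomalies | precip 30 % regional + 15 % site (multiplicative); tmax 1.2 / 0.5 °C (additive) | regional anomalies shared by all sites create the common signal (rbar) and the regional climate series; site noise decorrelates sites |
| base slopes | (0.20, −0.08, −0.12) index per SD | winter-precipitation-dominated response with negative temperature effects |
| tree noise | lognormal SD 0.15–0.30 | keeps tree-level R² in a plausible 0.3–0.8 range |
| ages | lognormal(log 75, 0.7), clipped 25–450 | inventory median near 75, long right tail for targeted selection |
| warming centers | (1.6, 3.1, 5.3) °C; precip factors (0.97, 0.94, 0.90) | high-emission-scenario trajectory; each GCM has one persistent sensitivity draw, so warming is monotone across periods by construction |

## Detrending

`fit_modified_negexp()` fits $a e^{-bt} + k$ by Levenberg–Marquardt. "Poor
fit" — non-convergence, $b \le 0$, $k < 0$, or a non-positive curve —
triggers a least-squares line; a line with non-negative slope is replaced
by the horizontal mean (biological growth curves do not increase with age;
the nonincreasing convention is flagged in the output). The curve is
floored at 0.001 mm before division so near-zero fitted values cannot blow
up the index.

`smoothing_spline()` is a discrete penalized smoothing spline
(second-difference penalty). Its stiffness is solved in closed form from
the 50 % frequency-cutoff criterion: the stationary amplitude response of
the penalized smoother is $H(f) = 1/(1 + 16\lambda\sin^4 \pi f)$, so
$\lambda = 1/(16 \sin^4(\pi/p))$ puts $H = 1/2$ exactly at wavelength $p$,
and $H > 0.95$ at $10p$ follows. The series is padded by point reflection
(2 cutoff lengths per end) before solving, then cropped; the response
measured by sinusoid regression over the interior is 0.500. Near the first
and last half-wavelength the smoother tracks the data more closely than
the stationary response — a property shared by the classical
frequency-cutoff splines of dendrochronology, where flexible ends are an
accepted cost.

`prewhiten()` fits an AR model with AIC-selected order (0–10, Yule–Walker)
and returns residuals re-centred on the input mean. ARMA alternatives were
considered and not used: AR is deterministic, order selection is stable,
and the robustness harness only needs autocorrelation removed. The leading
`order` values have no residual and are dropped; the collection wrapper
records the order per series and leaves sub-30-year series unwhitened.

## Tree-level sensitivity

Predictors are z-scored *per series* over its own in-window (1930–1995)
years, and the regression includes an intercept, so slopes are in index
units per predictor SD and comparable across trees; window years with any
missing value are dropped listwise. Regional equations written without an
intercept only make sense on centred variables — an intercept-free raw-unit
fit could not reproduce plausible explained variance, since RWI has mean
≈ 1 while ln(precipitation) and temperature do not. Per-region
standardization was the alternative; per-tree was chosen because the
tree-level statistics are compared across sites with different local
climates. Series with fewer than 30 in-window years are excluded (an `NA`
signal from `series_sd()`, a logged exclusion in the table builder). Age is
the mean cumulative ring count within the window, counted from the
innermost ring (no pith offset — unavailable in archive data; the generator
supplies the true pith year through the metadata).

## Local contrasts and the bootstrapped Wilcoxon test

Each targeted site's per-statistic median is contrasted against the median
over all same-species representative series within 100 km
(site-to-site distances, great-circle on a 6371 km sphere); focal sites
with fewer than 10 qualifying neighbors are discarded. Because the two
groups can differ greatly in size, each of 1000 iterations subsamples the
larger group without replacement to the smaller group's size and runs a
two-sided rank-sum test (normal approximation, tie-corrected); the reported
p is the median over iterations — a robust choice where only "bootstrapped"
is specified.

Two calibration facts, both verified in the test suite: (i) with
equal-sized groups the subsample is a permutation of the whole group, so
the procedure reduces *exactly* to a single rank-sum test, and its null
rejection rate at $\alpha = 0.01$ sits in the binomial band; (ii) with
unequal groups the median aggregation is conservative (measured null rate
≈ 0.001 at $\alpha = 0.01$ for 30 vs 50) — it under-rejects, never
over-rejects, so significant contrasts are if anything understated.

## Regional chronologies

Trees are averaged to site means, then site means to a regional value with
weights proportional to each site's mean distance to the other sites
*present that year* — isolated sites count more, and the weights adapt as
sites enter and leave the record. Variance stabilization scales deviations
from the chronology mean by $\sqrt{n_{\mathrm{eff}}(t)}$ with
$n_{\mathrm{eff}} = n_t / (1 + (n_t - 1)\bar r)$, anchored so the variance
over the maximum-replication years is unchanged and the mean is preserved
exactly; for equicorrelated series this removes the replication-driven
variance inflation identically (the variance of a mean of $n$ series with
common correlation $\bar r$ is $1/n_{\mathrm{eff}}$ times the series
variance). $\bar r$ is computed once over all pairs with ≥ 30 common years,
not per moving window, since a single value is what the stabilization
formula consumes. Regional *climate* series are deliberately not
stabilized. Stabilization is idempotent via a flag; $\bar r \le 0$ makes
the formula meaningless and passes through with a warning.

## Regional model and projection

The regional model regresses each chronology on standardized
$\ln(\text{cool-season precipitation})$ and standardized dry-season
maximum temperature (the mean of the prior-fall and current-summer series)
over 1902–2008, as one OLS fit with a database interaction — numerically
identical to two per-database fits, which is how the per-database adjusted
R² is reported.

Projection applies the fitted slopes to each future normal's standardized
anomalies: $z_P = \ln(\text{precip factor})/s_{\ln P}$ and
$z_T = \Delta T / s_T$, with $s_{\ln P}, s_T$ the calibration-window SDs.
Projected mean RWI is anchored at the baseline-window (1902–1999,
"twentieth-century") mean of the observed chronology, so null normals give
exactly zero decline; the decline percentage may exceed 100 when the linear
extrapolation goes negative. The anchoring choice (baseline mean rather
than the regression intercept) trades a sub-0.01 difference in level for an
exact null-change contract. Percent contrasts on printed-precision
coefficients round the slope difference to the input precision first
(`sensitivity_contrast_pct(0.161, 0.101)` → difference 0.06 → 59 %);
`rounded = FALSE` gives the raw ratio (0.041/0.098 → 41.8 %), and both
paths are documented because printed arithmetic and full-precision
arithmetic can disagree in the last digit.

## What the tests do and do not show

The acceptance suite checks, at one CPU and desk scale: the exact
printed-coefficient arithmetic; spline response 0.50 ± 0.02 at the cutoff;
negexp and slope recovery to 1e−6 on noiseless inputs; Wilcoxon null
calibration; the stabilized low/high-replication SD ratio in [0.8, 1.25];
the collinear geographic-weight hand case (0.275, 0.250, 0.475); and, on
the default 50-site, ~500-series landscape, the full sign structure —
targeted exceeds representative in median SD, median |β|, median R²,
chronology SD, and projected decline in all three periods. Multi-seed sign
tests (20 seeds, mini landscapes of 18 sites) confirm the direction is not
a single-seed accident, and the same contrasts keep their signs under all
six detrending variants (negexp/spline30/spline100 × ± prewhitening).

Problem sizes were chosen so the whole suite runs in about two minutes:
mini landscapes for the multi-seed loops, the full default landscape once.

What passing does **not** show: the generator has no dating error, missing
rings, disturbance pulses, CO₂ or stand-dynamics trends, nonlinear or
non-stationary climate response, and its chronologies are cleaner than real
ones — synthetic rbar, chronology R² and projected declines all run higher
than observational values. Conclusions transfer to real archives as
directions and mechanisms, not magnitudes.

## Known limitations

- The mixed-effects model of growth-variability drivers (age, database,
  geography, climate normals, with model selection) is out of scope here.
- Only AR prewhitening is offered; ARMA is not.
- No regional-curve standardization or signal-free detrending; ratio
  detrending removes low-frequency environmental signal along with the
  ontogenetic trend, and nothing here recovers it.
- Future normals are synthetic stand-ins with a single persistent
  per-GCM sensitivity; no real GCM output is read.
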