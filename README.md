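# ringbias

Tree-ring archives such as the International Tree-Ring Data Bank (ITRDB)
are dominated by *targeted* collections: old trees on warm, dry, rocky
sites, chosen to maximize the climate signal in their ring widths.
Forest-inventory networks (FIA-style) instead sample trees on a systematic
spatial grid, representatively. When climate–growth relationships fitted to
targeted collections are used to project forest growth under climate
change, the projection inherits the selection bias and overstates the
expected decline.

`ringbias` is an R package for quantifying that bias end to end. It
provides:

- a **synthetic-landscape generator** that emulates the documented biases —
  macro-site (low-elevation site selection), micro-site (dry, rocky
  micro-positions), and age (old-tree selection) — so every downstream stage
  has inputs with known ground truth;
- **Tucson decadal (`.rwl`) I/O** and monthly-climate CSV handling;
- **detrending** of raw ring widths to a ring-width index (RWI): a modified
  negative exponential `a·exp(−b·t) + k` with a line/mean fallback, or a
  smoothing spline with a 50 % frequency cutoff at 30 or 100 years, with
  optional AR prewhitening;
- **tree-level sensitivity**: per-series SD over the 1930–1995 window and an
  OLS regression of RWI on three standardized seasonal predictors —
  cool-season precipitation (prev. Nov–Mar), prior-fall maximum temperature
  (Aug–Oct), current-summer maximum temperature (May–Jul);
- **geographically local contrasts** of targeted vs representative medians
  within a 100 km same-species neighborhood, tested with a bootstrapped
  two-sided Wilcoxon rank-sum test (larger group subsampled, 1000
  iterations, median p);
- **regional chronologies** with per-year geographic weighting (weight ∝
  mean distance to the other sites present that year) and variance
  stabilization by effective sample size `n_eff = n / (1 + (n − 1)·r̄)`;
- a **regional climate–growth model** `RWI_t = β_P·z[ln(precip)]_t +
  β_T·z[tmax]_t` per database, and linear **projection** of future growth
  under synthetic GCM-ensemble climate normals, with the headline percent
  contrasts (e.g. `sensitivity_contrast_pct(0.161, 0.101)` = 59 %;
  `decline_contrast(106, 75)` = 29 % less decline / 41 % stronger
  reduction).

Everything is tidyverse-shaped: data frames in, tibbles out, `autoplot()`
methods for chronologies and projections, `tidy()`/`glance()` for the
regional model.

## Worked example

```r
library(ringbias)
library(dplyr)

run <- run_full_analysis(ring_config(seed = 1))
run
#> ring_run: 512 series at 50 sites (153 targeted / 359 representative)
#> sensitivity records: 422 | retained contrast sites: 14
#> chronology SD (targeted/representative): 0.469 / 0.232
#> Regional climate-growth model (calibration 1902-2008)
#> # A tibble: 2 × 6
#>   database       slope_lnprecip slope_tmax r2_adj  sigma n_years
#>   <chr>                   <dbl>      <dbl>  <dbl>  <dbl>   <int>
#> 1 targeted                0.363     -0.262  0.948 0.107      107
#> 2 representative          0.183     -0.130  0.970 0.0404     107
```

The targeted chronology is twice as variable (SD 0.469 vs 0.232) and its
climate slopes are roughly twice as steep — the synthetic landscape's
sampling bias, recovered by the pipeline. Projections diverge accordingly:

```r
run$projection_tests
#> # A tibble: 3 × 5
#>   period    mean_targeted mean_representative statistic  p_value
#>   <chr>             <dbl>               <dbl>     <dbl>    <dbl>
#> 1 2010-2039        0.0313              0.523      -9.54 5.23e- 9
#> 2 2040-2069       -0.857               0.0818    -13.2  1.72e-11
#> 3 2070-2099       -2.15               -0.562     -15.4  9.58e-13
```

Projected mean RWI based on the targeted sample collapses below zero by
mid-century while the representative projection declines far less, in every
period (two-sided t test across the 15-member GCM ensemble). Local
contrasts carry the same signal: `run$contrasts` holds the per-site median
contrasts (targeted − representative) for SD, the three slopes and R², with
bootstrapped Wilcoxon significance.

Individual stages compose with the pipe, e.g.:

```r
rwi  <- detrend(read_rwl("archive.rwl"), method = "negexp")
sens <- build_sensitivity_table(rwi, read_climate_csv("climate.csv"), meta)
site_contrasts(sens, radius_km = 100, min_neighbors = 10, seed = 1)
```

## Limitations

The synthetic generator produces archives that are *cleaner* than real
collections (no dating error, no disturbance pulses, purely linear climate
response), so absolute magnitudes — chronology R², rbar, percent declines —
run higher than observational values; the package's claims about real data
are directional, not quantitative. See the methods vignette
(`vignettes/sampling-bias-tree-rings.Rmd`) for the model, its assumptions,
and every tunable default.
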