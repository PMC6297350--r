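# Synthetic landscape, climate, and tree-ring archive generator.  The
# generator encodes the data-generating model the downstream analysis
# assumes -- an ontogenetic negative-exponential trend multiplied by a linear
# response to three seasonal climate predictors and lognormal noise -- plus
# the documented selection biases of targeted collections: preferential
# sampling of old trees (age bias), of low-elevation sites (macro-site bias),
# and of dry micro-sites (micro-site bias).

#' Landscape configuration
#'
#' @param n_sites Number of sites (>= 1).
#' @param lat_range,lon_range,elev_range Geographic ranges, decimal degrees
#'   and metres.  Degenerate ranges (lo == hi) are allowed.
#' @param aridity_gradient Unitless slope scaling how strongly the mean
#'   climate varies along (latitude, longitude, elevation); 0 gives a flat
#'   climate field.
#' @param seed Mandatory integer seed; identical seeds give identical
#'   landscapes.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(n_sites = 50,
                             lat_range = c(33, 37.5),
                             lon_range = c(-112, -107.5),
                             elev_range = c(1200, 3000),
                             aridity_gradient = 1,
                             seed = 1) {
  if (!is.numeric(n_sites) || n_sites < 1) stop("`n_sites` must be >= 1")
  check_range(lat_range, "lat_range")
  check_range(lon_range, "lon_range")
  check_range(elev_range, "elev_range")
  if (is.null(seed) || is.na(seed)) stop("`seed` is mandatory")
  structure(list(n_sites = as.integer(n_sites), lat_range = lat_range,
                 lon_range = lon_range, elev_range = elev_range,
                 aridity_gradient = aridity_gradient, seed = as.integer(seed)),
            class = "landscape_config")
}

#' Generate a virtual forested landscape
#'
#' Sites get coordinates, elevation (partly tied to latitude, so that
#' low-elevation sites cluster geographically in the south) and climate
#' normals that vary monotonically along the configured aridity gradient:
#' aridity rises with decreasing elevation, from north to south and from
#' west to east, and the cool-season precipitation normal falls (the
#' dry-season temperature normal rises) with aridity.
#'
#' @param config A [landscape_config()].
#' @return Tibble with `site_id`, `lat`, `lon`, `elev_m`, `aridity`,
#'   `precip_norm_mm` (cool-season total normal) and `tmax_norm_C`
#'   (dry-season mean maximum normal).
#' @export
make_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  n <- config$n_sites
  with_seed(config$seed, {
    lat <- runif(n, config$lat_range[1], config$lat_range[2])
    lon <- runif(n, config$lon_range[1], config$lon_range[2])
    latfrac <- if (diff(config$lat_range) == 0) rep(0.5, n) else
      (lat - config$lat_range[1]) / diff(config$lat_range)
    elev <- config$elev_range[1] +
      diff(config$elev_range) * pmin(1, pmax(0, 0.65 * latfrac + 0.35 * runif(n)))
    zf <- function(x) if (length(x) < 2 || sd(x) == 0) rep(0, n) else
      (x - mean(x)) / sd(x)
    aridity <- config$aridity_gradient *
      (-0.5 * zf(elev) - 0.35 * zf(lat) + 0.15 * zf(lon))
    tibble::tibble(
      site_id = sprintf("S%03d", seq_len(n)),
      lat = lat, lon = lon, elev_m = elev, aridity = aridity,
      precip_norm_mm = 160 * exp(-0.25 * aridity),
      tmax_norm_C = 24 + 2.2 * aridity
    )
  })
}

#' Generate monthly climate for a landscape
#'
#' Monthly precipitation and mean maximum temperature per site: a fixed
#' monthly climatology derived from the site normals, plus interannual
#' anomalies shared across the whole region and independent site-level
#' noise.  Precipitation anomalies are multiplicative and truncated at
#' zero; temperature anomalies are additive.
#'
#' @param sites Landscape table from [make_landscape()].
#' @param years Integer vector of at least 2 calendar years.
#' @param seed Integer seed.
#' @param sd_regional_precip,sd_site_precip Relative (multiplicative)
#'   monthly precipitation anomaly SDs, regional and site level.
#' @param sd_regional_tmax,sd_site_tmax Additive monthly temperature
#'   anomaly SDs, degrees C.
#' @return Tibble `site_id`, `year`, `month`, `precip_mm`, `tmax_C`.
#' @export
make_climate <- function(sites, years, seed,
                         sd_regional_precip = 0.30, sd_site_precip = 0.15,
                         sd_regional_tmax = 1.2, sd_site_tmax = 0.5) {
  stop_if_missing_cols(sites, c("site_id", "precip_norm_mm", "tmax_norm_C"),
                       "`sites`")
  years <- sort(unique(as.integer(years)))
  if (length(years) < 2) stop("need at least 2 years of climate")
  n_s <- nrow(sites)
  n_y <- length(years)
  months <- 1:12
  # cool-season months (Nov-Mar) each 0.2 of the cool-season normal
  w_p <- c(0.2, 0.2, 0.2, 0.04, 0.04, 0.04, 0.22, 0.22, 0.10, 0.08, 0.2, 0.2)
  seas_t <- 8 * cos(2 * pi * (months - 7) / 12)
  with_seed(seed, {
    reg_p <- matrix(rnorm(n_y * 12, 0, sd_regional_precip), n_y, 12)
    reg_t <- matrix(rnorm(n_y * 12, 0, sd_regional_tmax), n_y, 12)
    grid <- tidyr::expand_grid(site_id = sites$site_id, year = years,
                               month = months)
    iy <- match(grid$year, years)
    im <- grid$month
    is <- match(grid$site_id, sites$site_id)
    site_p <- rnorm(nrow(grid), 0, sd_site_precip)
    site_t <- rnorm(nrow(grid), 0, sd_site_tmax)
    p_norm <- sites$precip_norm_mm[is] * w_p[im]
    grid$precip_mm <- pmax(0, p_norm * (1 + reg_p[cbind(iy, im)] + site_p))
    grid$tmax_C <- sites$tmax_norm_C[is] + seas_t[im] +
      reg_t[cbind(iy, im)] + site_t
    grid
  })
}

#' Generate a tree population with ground-truth parameters
#'
#' Every tree carries the parameters that generate its ring widths: a
#' negative-exponential ontogenetic curve `(a, b, k)`, three climate-response
#' slopes in index units per standardized climate unit, a micro-site
#' multiplier (mean 1 = mesic micro-site; larger = drier, more climate
#' sensitive), and a lognormal noise SD.  Site aridity and tree age scale
#' the slopes: sensitivity increases with aridity and, through
#' `1 + age_gamma * log(age / 75)`, with age.
#'
#' @param sites Landscape table.
#' @param trees_per_site Trees generated per site.
#' @param seed Integer seed.
#' @param beta_precip,beta_fallT,beta_summerT Base slopes (index per SD of
#'   cool-season precipitation, prior-fall tmax, current-summer tmax).
#' @param age_gamma Age-sensitivity exponent (0 disables the age effect).
#' @param aridity_sensitivity Slope of the sensitivity multiplier on site
#'   aridity.
#' @param micro_sdlog Lognormal sdlog of the micro-site multiplier.
#' @param noise_range Uniform range of per-tree lognormal noise SD.
#' @param age_meanlog,age_sdlog,min_age,max_age Lognormal age distribution
#'   (years), clipped.
#' @return Tibble of `TreeTruth` records, one row per tree.
#' @export
simulate_population <- function(sites, trees_per_site = 40, seed = 1,
                                beta_precip = 0.20, beta_fallT = -0.08,
                                beta_summerT = -0.12, age_gamma = 0.3,
                                aridity_sensitivity = 0.35,
                                micro_sdlog = 0.2,
                                noise_range = c(0.15, 0.30),
                                age_meanlog = log(75), age_sdlog = 0.7,
                                min_age = 25, max_age = 450) {
  stop_if_missing_cols(sites, c("site_id", "aridity"), "`sites`")
  n <- nrow(sites) * trees_per_site
  with_seed(seed, {
    site_idx <- rep(seq_len(nrow(sites)), each = trees_per_site)
    age <- pmin(max_age, pmax(min_age,
                              round(rlnorm(n, age_meanlog, age_sdlog))))
    sens_site <- pmax(0.2, 1 + aridity_sensitivity * sites$aridity[site_idx])
    sens_age <- pmax(0.2, 1 + age_gamma * log(age / 75))
    s <- sens_site * sens_age
    tibble::tibble(
      tree_id = sprintf("TR%05d", seq_len(n)),
      site_id = sites$site_id[site_idx],
      age_years = as.integer(age),
      beta_precip = beta_precip * s,
      beta_fallT = beta_fallT * s,
      beta_summerT = beta_summerT * s,
      micro_multiplier = rlnorm(n, -micro_sdlog^2 / 2, micro_sdlog),
      negexp_a = runif(n, 1.5, 4), negexp_b = runif(n, 0.02, 0.08),
      negexp_k = runif(n, 0.2, 0.8),
      noise_sd = runif(n, noise_range[1], noise_range[2])
    )
  })
}

#' Representative (inventory-style) sampling
#'
#' Emulates a systematic plot network: plots are assigned to sites in a
#' spatially gridded round-robin over the landscape, and each plot cores
#' `1 + Poisson(trees_per_plot - 1)` trees drawn from the full population
#' age distribution at that site.
#'
#' @param population Tree-truth table from [simulate_population()].
#' @param sites Landscape table (for plot gridding).
#' @param n_plots Number of plots.
#' @param trees_per_plot Mean cored trees per plot (default 1.4, the
#'   inventory average).
#' @param seed Integer seed.
#' @return Tree-truth rows of the selected trees with `series_id` and
#'   `database = "representative"` added.
#' @export
sample_representative <- function(population, sites, n_plots = 250,
                                  trees_per_plot = 1.4, seed = 1) {
  if (nrow(population) == 0) stop("empty population")
  if (trees_per_plot < 1) stop("`trees_per_plot` must be >= 1")
  with_seed(seed, {
    # grid order: coarse lon bands swept by lat, so plots spread evenly
    ord <- order(round((sites$lon - min(sites$lon)) * 2), sites$lat)
    plot_sites <- rep(sites$site_id[ord], length.out = n_plots)
    n_trees <- if (trees_per_plot == 1) rep(1L, n_plots) else
      1L + rpois(n_plots, trees_per_plot - 1)
    need <- tapply(n_trees, plot_sites, sum)
    picked <- lapply(names(need), function(s) {
      pool <- which(population$site_id == s)
      pool[sample.int(length(pool), min(need[[s]], length(pool)))]
    })
    sel <- population[unlist(picked), ]
    sel$series_id <- sprintf("R%05d", seq_len(nrow(sel)))
    sel$database <- "representative"
    sel
  })
}

#' Targeted (climate-signal maximizing) sampling
#'
#' Emulates the classical dendroclimatological site and tree selection:
#' sites are drawn from the lowest `elev_quantile` of the elevation
#' distribution (macro-site bias), trees from the oldest `age_quantile` of
#' the site's age distribution (age bias), and the sampled trees' micro-site
#' multiplier is shifted upward by `micro_bias` (micro-site bias, trees on
#' steep rocky low-water-capacity spots).  With `age_quantile = 1`,
#' `elev_quantile = 1`, `micro_bias = 0` the draw is indistinguishable from
#' representative sampling in expectation.
#'
#' @param population Tree-truth table.
#' @param sites Landscape table.
#' @param n_sites,trees_per_site Sites sampled and trees cored per site.
#' @param age_quantile,elev_quantile Selection quantiles in (0, 1].
#' @param micro_bias Additive shift of the micro-site multiplier (>= 0).
#' @param seed Integer seed.
#' @return Tree-truth rows of the selected trees with `series_id` and
#'   `database = "targeted"` added.
#' @export
sample_targeted <- function(population, sites, n_sites = 15,
                            trees_per_site = 15, age_quantile = 0.25,
                            elev_quantile = 1 / 3, micro_bias = 0.4,
                            seed = 1) {
  if (nrow(population) == 0) stop("empty population")
  if (age_quantile <= 0 || age_quantile > 1 ||
      elev_quantile <= 0 || elev_quantile > 1) {
    stop("selection quantiles must lie in (0, 1]")
  }
  with_seed(seed, {
    elig <- if (elev_quantile >= 1) sites else
      sites[sites$elev_m <= quantile(sites$elev_m, elev_quantile), ]
    chosen <- elig$site_id[sample.int(nrow(elig), min(n_sites, nrow(elig)))]
    picked <- lapply(chosen, function(s) {
      pool <- population[population$site_id == s, ]
      if (age_quantile < 1) {
        cut <- quantile(pool$age_years, 1 - age_quantile)
        pool <- pool[pool$age_years >= cut, ]
      }
      pool[sample.int(nrow(pool), min(trees_per_site, nrow(pool))), ]
    })
    sel <- dplyr::bind_rows(picked)
    sel$micro_multiplier <- sel$micro_multiplier + micro_bias
    sel$series_id <- sprintf("T%05d", seq_len(nrow(sel)))
    sel$database <- "targeted"
    sel
  })
}

#' Simulate dated ring-width series from tree truth
#'
#' Generates `width_t = (a e^{-b t} + k) * max(clip_floor, 1 + m (b_P z_P +
#' b_F z_F + b_S z_S)) * eps_t` with `eps` lognormal(0, `noise_sd`), where
#' `t` is cambial age, `m` the micro-site multiplier, and the `z` are the
#' site's seasonal climate predictors standardized over `std_window`.
#' Trees are assumed alive in the last simulated year; older trees extend
#' further back (clipped to the climate record).
#'
#' @param truth Tree-truth rows (one or many) carrying `series_id` (or
#'   `tree_id`), `site_id`, ontogenetic and response parameters.
#' @param climate Monthly climate table covering the simulation years.
#' @param years Years to simulate; default all years resolvable from the
#'   climate (the first calendar year is lost to the prior-year predictors).
#' @param seed Integer seed.
#' @param std_window Years over which the seasonal predictors are
#'   standardized (default: all simulated years).
#' @param clip_floor Lower clip of the relative climate response (default
#'   0.05, keeping widths positive); set to `-Inf` to disable clipping.
#' @return Tibble `series_id`, `site_id`, `year`, `width_mm`.
#' @export
simulate_tree_series <- function(truth, climate, years = NULL, seed = 1,
                                 std_window = NULL, clip_floor = 0.05) {
  stop_if_missing_cols(truth, c("site_id", "age_years", "beta_precip",
                                "beta_fallT", "beta_summerT",
                                "micro_multiplier", "negexp_a", "negexp_b",
                                "negexp_k", "noise_sd"), "`truth`")
  if (any(truth$negexp_a <= 0 | truth$negexp_b <= 0 | truth$negexp_k < 0)) {
    stop("non-positive negative-exponential curve parameters")
  }
  if (!"series_id" %in% names(truth)) truth$series_id <- truth$tree_id
  seas <- seasonal_predictors(climate)
  if (is.null(years)) years <- sort(unique(seas$year))
  years <- sort(intersect(as.integer(years), seas$year))
  if (!length(years)) stop("no simulatable years: climate does not cover `years`")
  if (is.null(std_window)) std_window <- range(years)
  zs <- seas |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(dplyr::across(
      c("precip_cool", "tmax_fall_prev", "tmax_summer"),
      function(x) {
        inw <- .data$year >= std_window[1] & .data$year <= std_window[2]
        (x - mean(x[inw])) / sd(x[inw])
      },
      .names = "z_{.col}"
    )) |>
    dplyr::ungroup()
  last_year <- max(years)
  with_seed(seed, {
    out <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      birth <- last_year - tr$age_years + 1L
      yrs <- years[years >= birth]
      if (!length(yrs)) stop("tree ", tr$series_id,
                             ": lifespan does not overlap climate years")
      z <- zs[zs$site_id == tr$site_id & zs$year %in% yrs, ]
      z <- z[order(z$year), ]
      t_age <- z$year - birth + 1L
      curve <- tr$negexp_a * exp(-tr$negexp_b * t_age) + tr$negexp_k
      clim <- 1 + tr$micro_multiplier *
        (tr$beta_precip * z$z_precip_cool +
           tr$beta_fallT * z$z_tmax_fall_prev +
           tr$beta_summerT * z$z_tmax_summer)
      eps <- if (tr$noise_sd > 0) rlnorm(length(t_age), 0, tr$noise_sd) else 1
      out[[i]] <- tibble::tibble(
        series_id = tr$series_id, site_id = tr$site_id, year = z$year,
        width_mm = curve * pmax(clip_floor, clim) * eps
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Synthetic future climate normals
#'
#' Stands in for an ensemble of GCM projections under a high-emission
#' scenario: each GCM gets a persistent sensitivity draw, warming
#' (`delta_tmax`, degrees C relative to the calibration mean) scales up
#' period by period by construction, and the precipitation multiplier drifts
#' below 1.
#'
#' @param n_gcms Number of GCMs (>= 1), default 15.
#' @param periods Character period labels.
#' @param seed Integer seed.
#' @param warming Central warming per period (degrees C), strictly
#'   increasing.
#' @param precip_trend Central precipitation factor per period.
#' @param scenario Scenario label.
#' @return Tibble with one record per (gcm_id, period).
#' @export
make_future_normals <- function(n_gcms = 15,
                                periods = c("2010-2039", "2040-2069",
                                            "2070-2099"),
                                seed = 1,
                                warming = c(1.6, 3.1, 5.3),
                                precip_trend = c(0.97, 0.94, 0.90),
                                scenario = "RCP8.5") {
  if (n_gcms < 1) stop("`n_gcms` must be >= 1")
  if (length(warming) != length(periods) ||
      length(precip_trend) != length(periods)) {
    stop("`warming` and `precip_trend` must match `periods` in length")
  }
  with_seed(seed, {
    u <- pmin(3, pmax(-3, rnorm(n_gcms)))
    v <- pmin(3, pmax(-3, rnorm(n_gcms)))
    tidyr::expand_grid(gcm_id = sprintf("GCM%02d", seq_len(n_gcms)),
                       period = periods) |>
      dplyr::mutate(
        scenario = scenario,
        delta_tmax = warming[match(.data$period, periods)] *
          exp(0.15 * u[match(.data$gcm_id, sprintf("GCM%02d", seq_len(n_gcms)))]),
        precip_factor = precip_trend[match(.data$period, periods)] *
          exp(0.05 * v[match(.data$gcm_id, sprintf("GCM%02d", seq_len(n_gcms)))])
      )
  })
}
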