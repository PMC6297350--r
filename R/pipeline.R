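# Orchestration: one configuration object, one function running
# simulate -> detrend -> sensitivity -> contrast -> chronology -> projection,
# with every stage output returned and optionally written to disk with a
# manifest of all seeds and parameters.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with defaults equal to the study
#' constants: 1930-1995 analysis window, 100 km radius, minimum 10
#' neighbors, alpha 0.01, 1000 bootstrap iterations, 38 degrees N regional
#' cutoff, 1902-2008 calibration and 1902-1999 baseline windows, 15 GCMs
#' over three 30-year periods.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param n_sites,trees_per_site Landscape size and population density.
#' @param years Simulated calendar years.
#' @param n_plots,trees_per_plot Representative sampling design.
#' @param targeted_sites,targeted_trees_per_site,age_quantile,elev_quantile,micro_bias
#'   Targeted sampling design.
#' @param detrend_method,prewhiten Detrending choice.
#' @param window Tree-level analysis window.
#' @param radius_km,min_neighbors,alpha,iterations Contrast parameters.
#' @param lat_max Regional latitude cutoff.
#' @param calib_window,baseline Regional model calibration and baseline
#'   windows.
#' @param n_gcms,periods Future-normal ensemble.
#' @param ... Extra named entries passed through to the config.
#' @return A `ring_config` list.
#' @export
ring_config <- function(seed = 1,
                        n_sites = 50, trees_per_site = 40,
                        years = 1900:2008,
                        n_plots = 250, trees_per_plot = 1.4,
                        targeted_sites = 15, targeted_trees_per_site = 15,
                        age_quantile = 0.25, elev_quantile = 1 / 3,
                        micro_bias = 0.4,
                        detrend_method = "negexp", prewhiten = FALSE,
                        window = c(1930, 1995),
                        radius_km = 100, min_neighbors = 10, alpha = 0.01,
                        iterations = 1000,
                        lat_max = 38,
                        calib_window = c(1902, 2008),
                        baseline = c(1902, 1999),
                        n_gcms = 15,
                        periods = c("2010-2039", "2040-2069", "2070-2099"),
                        ...) {
  structure(c(as.list(environment()), list(...)), class = "ring_config")
}

derive_seed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2147483629L

#' Run the full sampling-bias analysis
#'
#' Simulates a biased synthetic archive and runs every downstream stage:
#' detrending, tree-level sensitivity, local contrasts, regional
#' chronologies (geographically weighted, variance-stabilized), the
#' regional climate-growth model, and projection under synthetic future
#' normals.  Identical config and seed give identical outputs.
#'
#' @param config A [ring_config()].
#' @param out_dir Optional directory; when given, all stage tables, the
#'   ring-width archive (`.rwl`), and a JSON manifest (config, seeds,
#'   package version, config hash) are written there.
#' @return A `ring_run` list with all stage outputs.
#' @export
run_full_analysis <- function(config = ring_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ring_config"))
  cfg <- config
  lc <- landscape_config(n_sites = cfg$n_sites, seed = derive_seed(cfg$seed, 1L))
  sites <- make_landscape(lc)
  climate <- make_climate(sites, cfg$years, seed = derive_seed(cfg$seed, 2L))
  pop <- simulate_population(sites, trees_per_site = cfg$trees_per_site,
                             seed = derive_seed(cfg$seed, 3L))
  rep_sample <- sample_representative(pop, sites, n_plots = cfg$n_plots,
                                      trees_per_plot = cfg$trees_per_plot,
                                      seed = derive_seed(cfg$seed, 4L))
  targ_sample <- sample_targeted(pop, sites, n_sites = cfg$targeted_sites,
                                 trees_per_site = cfg$targeted_trees_per_site,
                                 age_quantile = cfg$age_quantile,
                                 elev_quantile = cfg$elev_quantile,
                                 micro_bias = cfg$micro_bias,
                                 seed = derive_seed(cfg$seed, 5L))
  collection <- dplyr::bind_rows(targ_sample, rep_sample)
  rw <- simulate_tree_series(collection, climate,
                             seed = derive_seed(cfg$seed, 6L),
                             std_window = cfg$window)
  last_year <- max(rw$year)
  meta <- collection |>
    dplyr::left_join(sites[c("site_id", "lat", "lon", "elev_m")],
                     by = "site_id") |>
    dplyr::mutate(
      species = species_band(.data$site_id, sites),
      pith_year = last_year - .data$age_years + 1L
    ) |>
    dplyr::select("series_id", "site_id", "lat", "lon", "elev_m", "species",
                  "database", "pith_year", "age_years")
  rwi <- detrend(rw, method = cfg$detrend_method, prewhiten = cfg$prewhiten)
  seasonal <- seasonal_predictors(climate)
  sens <- build_sensitivity_table(rwi, seasonal, meta, window = cfg$window)
  contrasts <- site_contrasts(sens, radius_km = cfg$radius_km,
                              min_neighbors = cfg$min_neighbors,
                              iterations = cfg$iterations, alpha = cfg$alpha,
                              seed = derive_seed(cfg$seed, 7L))
  split_ids <- split(meta$series_id, meta$database)
  chron <- lapply(c(targeted = "targeted", representative = "representative"),
                  function(db) {
    r <- rwi[rwi$series_id %in% split_ids[[db]], ]
    rb <- rbar(r, min_overlap = 30)
    ch <- build_regional_chronology(r, meta, lat_max = cfg$lat_max)
    list(chronology = variance_stabilize(ch, rb), rbar = rb)
  })
  regclim <- regional_climate(climate, sites, lat_max = cfg$lat_max)
  model <- fit_regional_model(chron$targeted$chronology,
                              chron$representative$chronology,
                              regclim, window = cfg$calib_window)
  normals <- make_future_normals(n_gcms = cfg$n_gcms, periods = cfg$periods,
                                 seed = derive_seed(cfg$seed, 8L))
  projection <- project_growth(model, normals, baseline = cfg$baseline)
  proj_tests <- compare_projection_distributions(projection)
  run <- structure(list(
    config = cfg, sites = sites, climate = climate, population = pop,
    collection = collection, rw = rw, meta = meta, rwi = rwi,
    sensitivity = sens, contrasts = contrasts,
    chronology_targeted = chron$targeted$chronology,
    chronology_representative = chron$representative$chronology,
    rbar_targeted = chron$targeted$rbar,
    rbar_representative = chron$representative$rbar,
    regional_climate = regclim, model = model, normals = normals,
    projection = projection, projection_tests = proj_tests
  ), class = "ring_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Species assignment by elevation band: pinyon low, ponderosa mid,
# Douglas-fir high -- a coarse sketch of Southwest zonation used so that
# same-species neighborhood filtering has something to act on.
species_band <- function(site_id, sites) {
  el <- sites$elev_m[match(site_id, sites$site_id)]
  q <- quantile(sites$elev_m, c(1 / 3, 2 / 3))
  dplyr::case_when(el <= q[1] ~ "PIED", el <= q[2] ~ "PIPO", TRUE ~ "PSME")
}

#' Regional average monthly climate, seasonally aggregated
#'
#' Averages monthly climate over the sites of the region (optionally
#' latitude-filtered) and returns the seasonal predictor table of the
#' resulting regional series.  Regional climate variance is deliberately
#' not adjusted for site replication.
#'
#' @param climate Monthly climate table.
#' @param sites Landscape/site table with `site_id`, `lat`.
#' @param lat_max Optional northern cutoff.
#' @return Seasonal predictor tibble for the pseudo-site `"region"`.
#' @export
regional_climate <- function(climate, sites, lat_max = NULL) {
  keep <- if (is.null(lat_max)) sites$site_id else
    sites$site_id[sites$lat < lat_max]
  reg <- climate[climate$site_id %in% keep, ] |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(precip_mm = mean(.data$precip_mm),
                     tmax_C = mean(.data$tmax_C), .groups = "drop") |>
    dplyr::mutate(site_id = "region")
  seasonal_predictors(reg) |> dplyr::select(-"site_id")
}

#' @export
print.ring_run <- function(x, ...) {
  cat("ring_run: ", nrow(x$meta), " series at ", nrow(x$sites), " sites (",
      sum(x$meta$database == "targeted"), " targeted / ",
      sum(x$meta$database == "representative"), " representative)\n",
      sep = "")
  cat("sensitivity records:", nrow(x$sensitivity),
      "| retained contrast sites:",
      length(unique(x$contrasts$focal_site_id)), "\n")
  cat("chronology SD (targeted/representative): ",
      round(sd(x$chronology_targeted$value), 3), " / ",
      round(sd(x$chronology_representative$value), 3), "\n", sep = "")
  print(x$model)
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_rwl(run$rw, p("ringwidths.rwl"))
  readr::write_csv(run$meta, p("series_meta.csv"))
  readr::write_csv(run$climate, p("climate_monthly.csv"))
  readr::write_csv(run$collection, p("tree_truth.csv"))
  readr::write_csv(run$sensitivity, p("sensitivity.csv"))
  readr::write_csv(run$contrasts, p("contrasts.csv"))
  readr::write_csv(tibble::as_tibble(run$chronology_targeted),
                   p("chronology_targeted.csv"))
  readr::write_csv(tibble::as_tibble(run$chronology_representative),
                   p("chronology_representative.csv"))
  readr::write_csv(run$projection, p("projection.csv"))
  readr::write_csv(run$projection_tests, p("projection_tests.csv"))
  jsonlite::write_json(run$normals, p("future_normals.json"),
                       dataframe = "rows", digits = NA)
  cfg <- run$config
  manifest <- list(
    package = "ringbias",
    version = as.character(utils::packageVersion("ringbias")),
    config = cfg[setdiff(names(cfg), "years")],
    years = range(cfg$years),
    config_hash = rlang::hash(unclass(cfg)),
    rbar = list(targeted = run$rbar_targeted,
                representative = run$rbar_representative)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
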