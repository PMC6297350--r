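# Small programmatic fixtures shared across test files.

tiny_landscape <- function(n = 12, seed = 42, ...) {
  make_landscape(landscape_config(n_sites = n, seed = seed, ...))
}

# Noise-free climate: anomalies off, so every year repeats the climatology.
flat_climate <- function(sites, years) {
  make_climate(sites, years, seed = 1,
               sd_regional_precip = 0, sd_site_precip = 0,
               sd_regional_tmax = 0, sd_site_tmax = 0)
}

# One-row tree-truth tibble with explicit parameters.
tree_truth <- function(site_id, age = 80, bP = 0.2, bF = -0.08, bS = -0.12,
                       micro = 1, a = 2, b = 0.05, k = 0.5, noise = 0,
                       id = "T00001") {
  tibble::tibble(series_id = id, tree_id = id, site_id = site_id,
                 age_years = as.integer(age), beta_precip = bP,
                 beta_fallT = bF, beta_summerT = bS, micro_multiplier = micro,
                 negexp_a = a, negexp_b = b, negexp_k = k, noise_sd = noise)
}

# Monthly climate for a single synthetic site as a plain tibble.
constant_climate <- function(years, precip = 10, tmax = 20,
                             site_id = "SITE1") {
  tidyr::expand_grid(site_id = site_id, year = years, month = 1:12) |>
    dplyr::mutate(precip_mm = precip, tmax_C = tmax)
}

# A small mini-pipeline configuration that runs in a couple of seconds.
mini_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_sites = 18, trees_per_site = 18, n_plots = 70,
         targeted_sites = 7, targeted_trees_per_site = 8, iterations = 50),
    list(...))
  do.call(ring_config, args)
}

# Re-wrap a plain tibble as an unstabilized chronology (subsetting drops
# the class attributes).
new_chron_for_test <- function(tbl) {
  ringbias:::new_chronology(tibble::as_tibble(tbl))
}

# Medians of the tree-level statistics by database, for sign checks.
sens_medians <- function(sens) {
  sens |>
    dplyr::group_by(database) |>
    dplyr::summarise(sd = median(sd), b_precip = median(abs(beta_precip)),
                     b_fallT = median(abs(beta_fallT)),
                     b_summerT = median(abs(beta_summerT)),
                     r2 = median(r2), .groups = "drop")
}
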