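test_that("geographic weights reward isolated sites", {
  one <- geographic_weights(tibble::tibble(site_id = "A", lat = 35,
                                           lon = -110))
  expect_equal(one$weight, 1)
  # collinear equatorial sites at 0, d, 10d: hand-computed mean distances
  # (5.5d, 5d, 9.5d) normalize to (0.275, 0.250, 0.475)
  coll <- tibble::tibble(site_id = c("A", "B", "C"), lat = 0,
                         lon = c(0, 0.5, 5))
  expect_equal(geographic_weights(coll)$weight, c(0.275, 0.25, 0.475),
               tolerance = 1e-9)
  # near-equilateral triangle: symmetric weights
  tri <- tibble::tibble(site_id = c("A", "B", "C"),
                        lat = c(0, 0, 0.0866), lon = c(-0.05, 0.05, 0))
  expect_equal(geographic_weights(tri)$weight, rep(1 / 3, 3),
               tolerance = 0.005)
  # coincident sites degrade gracefully to equal weights
  dup <- tibble::tibble(site_id = c("A", "B"), lat = 35, lon = -110)
  expect_equal(geographic_weights(dup)$weight, c(0.5, 0.5))
})

chron_fixture <- function() {
  meta <- tibble::tibble(series_id = c("s1", "s2", "s3"),
                         site_id = c("A", "A", "B"),
                         lat = c(0, 0, 0), lon = c(0, 0, 0.5))
  rwi <- dplyr::bind_rows(
    tibble::tibble(series_id = "s1", year = 2000:2004, rwi = c(1, 2, 3, 2, 1)),
    tibble::tibble(series_id = "s2", year = 2000:2004, rwi = c(3, 2, 1, 2, 3)),
    tibble::tibble(series_id = "s3", year = 2000:2003, rwi = c(4, 4, 4, 4)))
  list(rwi = rwi, meta = meta)
}

test_that("regional chronology is the per-year weighted mean of site means", {
  fx <- chron_fixture()
  ch <- build_regional_chronology(fx$rwi, fx$meta)
  # two equidistant sites: weights 1/2 each while both present
  expect_equal(ch$value[1:4], (2 + 4) / 2 + numeric(4))
  # year 2004: site B absent, weights renormalize onto site A alone
  expect_equal(ch$value[5], 2)
  expect_equal(ch$n_t, c(3, 3, 3, 3, 2))
  expect_equal(ch$site_count, c(2, 2, 2, 2, 1))
  # all series identical: chronology equals the common series
  same <- dplyr::mutate(fx$rwi, rwi = rep(c(1, 1.2, 0.8, 1.1, 0.9),
                                          length.out = dplyr::n()))
  same <- dplyr::group_by(same, year) |>
    dplyr::mutate(rwi = dplyr::first(rwi)) |> dplyr::ungroup()
  ch2 <- build_regional_chronology(same, fx$meta)
  expect_equal(ch2$value, same$rwi[match(ch2$year, same$year)])
  # weighted-mean bounds: every value within the site-mean range that year
  expect_error(build_regional_chronology(fx$rwi, fx$meta, lat_max = -10),
               "empty region")
})

test_that("chronology values stay inside the contributing site-mean envelope", {
  sites <- tiny_landscape(n = 6, seed = 31)
  clim <- make_climate(sites, 1950:2000, seed = 32)
  pop <- simulate_population(sites, trees_per_site = 5, seed = 33)
  rw <- simulate_tree_series(pop, clim, seed = 34)
  rwi <- detrend(rw, "negexp")
  meta <- dplyr::distinct(rw, series_id, site_id) |>
    dplyr::left_join(sites[c("site_id", "lat", "lon")], by = "site_id")
  ch <- build_regional_chronology(rwi, meta)
  site_year <- rwi |>
    dplyr::inner_join(meta, by = "series_id") |>
    dplyr::group_by(site_id, year) |>
    dplyr::summarise(m = mean(rwi), .groups = "drop") |>
    dplyr::group_by(year) |>
    dplyr::summarise(lo = min(m), hi = max(m), .groups = "drop")
  j <- dplyr::inner_join(tibble::as_tibble(ch), site_year, by = "year")
  expect_true(all(j$value >= j$lo - 1e-12 & j$value <= j$hi + 1e-12))
})

test_that("rbar averages qualifying pairwise correlations", {
  yrs <- 1950:1999
  base <- tibble::tibble(series_id = "a", year = yrs, rwi = sin(yrs / 3))
  same <- dplyr::mutate(base, series_id = "b")
  anti <- dplyr::mutate(base, series_id = "b", rwi = -rwi)
  expect_equal(rbar(dplyr::bind_rows(base, same)), 1)
  expect_equal(rbar(dplyr::bind_rows(base, anti)), -1)
  # three series: rbar equals the mean of the three direct correlations
  set.seed(41)
  m <- sapply(1:3, function(i) sqrt(0.4) * sin(yrs / 3) +
                sqrt(0.6) * rnorm(50))
  rwi3 <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(series_id = letters[i], year = yrs, rwi = m[, i])
  })
  direct <- cor(m)
  expect_equal(rbar(rwi3), mean(direct[upper.tri(direct)]), tolerance = 1e-12)
  # pairs below the overlap threshold are ignored
  short <- dplyr::bind_rows(base, dplyr::mutate(base[1:10, ], series_id = "c"))
  expect_error(rbar(dplyr::bind_rows(short[short$series_id == "c", ],
                                     base[1:10, ])), "overlapping")
})

test_that("variance stabilization equalizes replication-driven variance", {
  r <- 0.05
  n_hi <- 50; n_lo <- 5
  yrs_hi <- 1:220; yrs_lo <- 221:440
  set.seed(51)
  common <- rnorm(440)
  rwi <- purrr::map_dfr(seq_len(n_hi), function(i) {
    yrs <- if (i <= n_lo) 1:440 else yrs_hi
    tibble::tibble(series_id = sprintf("s%02d", i), year = yrs,
                   rwi = 1 + 0.2 * (sqrt(r) * common[yrs] +
                                      sqrt(1 - r) * rnorm(length(yrs))))
  })
  meta <- tibble::tibble(series_id = sprintf("s%02d", 1:n_hi),
                         site_id = "A", lat = 35, lon = -110)
  ch <- build_regional_chronology(rwi, meta)
  sd_ratio <- function(x) sd(x$value[x$year %in% yrs_lo]) /
    sd(x$value[x$year %in% yrs_hi])
  expect_gt(sd_ratio(ch), 1.5)
  st <- variance_stabilize(ch, rbar = r)
  expect_true(sd_ratio(st) > 0.8 && sd_ratio(st) < 1.25)
  # mean preserved, idempotent, and a no-op when replication is constant
  expect_equal(mean(st$value), mean(ch$value), tolerance = 1e-9)
  expect_identical(variance_stabilize(st, r)$value, st$value)
  const <- ch[ch$year %in% yrs_hi, ]
  expect_equal(variance_stabilize(new_chron_for_test(const), r)$value,
               const$value, tolerance = 1e-12)
  expect_warning(out <- variance_stabilize(ch, rbar = -0.1), "undefined")
  expect_identical(out$value, ch$value)
})

test_that("chronology statistics match autoregressive theory", {
  set.seed(61)
  wn <- tibble::tibble(year = 1:1000, value = rnorm(1000))
  s <- chronology_stats(wn)
  expect_lt(abs(s$acf1), 2 / sqrt(1000))
  ar1 <- tibble::tibble(year = 1:1000,
                        value = as.numeric(arima.sim(list(ar = 0.4), 1000)))
  s1 <- chronology_stats(ar1)
  expect_lt(abs(s1$acf1 - 0.4), 0.06)
  expect_lt(abs(s1$pacf2), 0.06)
  ar2 <- tibble::tibble(year = 1:2000,
                        value = as.numeric(arima.sim(list(ar = c(0.3, 0.25)),
                                                     2000)))
  expect_lt(abs(chronology_stats(ar2)$pacf2 - 0.25), 0.06)
  expect_error(chronology_stats(wn[1:5, ]), "10 years")
})

test_that("the resampling envelope collapses as the draw approaches the pool", {
  sites <- tiny_landscape(n = 4, seed = 71)
  clim <- make_climate(sites, 1960:2000, seed = 72)
  pop <- simulate_population(sites, trees_per_site = 8, seed = 73)
  rw <- simulate_tree_series(pop, clim, seed = 74)
  rwi <- detrend(rw, "negexp")
  meta <- dplyr::distinct(rw, series_id, site_id) |>
    dplyr::left_join(sites[c("site_id", "lat", "lon")], by = "site_id")
  pool <- dplyr::n_distinct(rwi$series_id)
  full <- resample_envelope(rwi, meta, target_n = pool, replicates = 10,
                            seed = 1)
  expect_true(all(full$hi - full$lo < 1e-12))
  expect_true(all(full$sd < 1e-12))
  small <- resample_envelope(rwi, meta, target_n = 5, replicates = 30,
                             seed = 2)
  large <- resample_envelope(rwi, meta, target_n = pool - 2, replicates = 30,
                             seed = 2)
  expect_gt(mean(small$sd), mean(large$sd))
  expect_identical(resample_envelope(rwi, meta, 5, 10, seed = 3),
                   resample_envelope(rwi, meta, 5, 10, seed = 3))
  expect_error(resample_envelope(rwi, meta, pool + 1), "pool")
})
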