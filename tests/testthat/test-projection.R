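# Build a regional-model fixture whose chronologies are exact linear
# functions of the standardized predictors.
exact_model <- function(bP_t = 0.3, bT_t = -0.2, bP_r = 0.15, bT_r = -0.1,
                        years = 1902:2008, seed = 1) {
  set.seed(seed)
  clim <- tibble::tibble(year = years,
                         precip_cool = exp(rnorm(length(years), log(150), 0.2)),
                         tmax_fall_prev = rnorm(length(years), 24, 1),
                         tmax_summer = rnorm(length(years), 30, 1))
  lnp <- log(clim$precip_cool)
  tmx <- (clim$tmax_fall_prev + clim$tmax_summer) / 2
  z <- function(x) (x - mean(x)) / sd(x)
  mk <- function(bP, bT) new_chron_for_test(
    tibble::tibble(year = years, value = 1 + bP * z(lnp) + bT * z(tmx),
                   n_t = 20L, site_count = 5L))
  list(t = mk(bP_t, bT_t), r = mk(bP_r, bT_r), clim = clim)
}

test_that("the regional model recovers exact generating slopes", {
  fx <- exact_model()
  m <- suppressWarnings(fit_regional_model(fx$t, fx$r, fx$clim))
  sm <- glance(m)
  expect_equal(sm$slope_lnprecip[sm$database == "targeted"], 0.3,
               tolerance = 1e-10)
  expect_equal(sm$slope_tmax[sm$database == "targeted"], -0.2,
               tolerance = 1e-10)
  expect_equal(sm$slope_lnprecip[sm$database == "representative"], 0.15,
               tolerance = 1e-10)
  expect_equal(sm$r2_adj, c(1, 1), tolerance = 1e-9)
  # the interaction fit and two separate per-database fits agree
  cf <- coef(m$fit)
  expect_equal(unname(cf[["databasetargeted:zlnp"]]), 0.3, tolerance = 1e-10)
  expect_equal(unname(cf[["databaserepresentative:ztmax"]]), -0.1,
               tolerance = 1e-10)
  td <- suppressWarnings(tidy(m))
  expect_equal(nrow(td), 6)
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
})

test_that("identical chronologies produce a zero database contrast", {
  fx <- exact_model(bP_t = 0.2, bT_t = -0.1, bP_r = 0.2, bT_r = -0.1)
  sm <- glance(suppressWarnings(fit_regional_model(fx$t, fx$r, fx$clim)))
  expect_equal(diff(sm$slope_lnprecip), 0, tolerance = 1e-12)
  expect_equal(diff(sm$slope_tmax), 0, tolerance = 1e-12)
})

test_that("regional model guards its domain", {
  fx <- exact_model()
  bad <- dplyr::mutate(fx$clim,
                       precip_cool = ifelse(year == 1950, 0, precip_cool))
  expect_error(fit_regional_model(fx$t, fx$r, bad), "log")
  short <- exact_model(years = 1990:2008)
  expect_error(fit_regional_model(short$t, short$r, short$clim), "30 years")
})

test_that("printed-coefficient contrast arithmetic is reproduced exactly", {
  p <- sensitivity_contrast_pct(0.161, 0.101)
  expect_equal(as.numeric(p), 59)
  expect_equal(attr(p, "difference"), 0.06)
  expect_equal(as.numeric(sensitivity_contrast_pct(0.5, 0.5)), 0)
  expect_equal(round(sensitivity_contrast_pct(0.139, 0.098, rounded = FALSE),
                     1), 41.8)
  expect_error(sensitivity_contrast_pct(0.1, 0), "zero")
  dc <- decline_contrast(106, 75)
  expect_equal(dc$less_decline_pct, 29)
  expect_equal(dc$stronger_reduction_pct, 41)
  expect_equal(unlist(decline_contrast(50, 25), use.names = FALSE),
               c(50, 100))
  expect_equal(unlist(decline_contrast(80, 80), use.names = FALSE), c(0, 0))
  expect_error(decline_contrast(0, 10), "positive")
})

test_that("projection is anchored, linear, and monotone in slope steepness", {
  fx <- exact_model()
  m <- suppressWarnings(fit_regional_model(fx$t, fx$r, fx$clim))
  null_norm <- tidyr::expand_grid(gcm_id = sprintf("G%02d", 1:5),
                                  period = c("P1", "P2")) |>
    dplyr::mutate(delta_tmax = 0, precip_factor = 1)
  pr <- project_growth(m, null_norm)
  expect_equal(pr$decline_pct, rep(0, nrow(pr)), tolerance = 1e-9)
  # hand case: unit scalings, slopes (0.16, -0.14), anomalies zP=-1, zT=+2
  hand <- structure(list(
    summary = tibble::tibble(database = "targeted", slope_lnprecip = 0.16,
                             slope_tmax = -0.14),
    scaling = list(sd_lnp = 1, sd_tmax = 1),
    data = tibble::tibble(database = "targeted", year = 1950, value = 1)
  ), class = "regional_model")
  hn <- tibble::tibble(gcm_id = "G", period = "P", scenario = "S",
                       delta_tmax = 2, precip_factor = exp(-1))
  hp <- project_growth(hand, hn, baseline = c(1900, 2000))
  expect_equal(hp$mean_rwi, 1 - 0.16 - 0.28, tolerance = 1e-12)
  expect_equal(hp$decline_pct, 44, tolerance = 1e-9)
  # linearity: doubling an anomaly doubles its contribution
  h2 <- dplyr::mutate(hn, delta_tmax = 4, precip_factor = 1)
  h1 <- dplyr::mutate(hn, delta_tmax = 2, precip_factor = 1)
  d2 <- project_growth(hand, h2, c(1900, 2000))$decline_pct
  d1 <- project_growth(hand, h1, c(1900, 2000))$decline_pct
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # steeper slopes never project less decline under warming/drying normals
  warm <- tibble::tibble(gcm_id = "G", period = "P", scenario = "S",
                         delta_tmax = 3, precip_factor = 0.9)
  grid <- tidyr::expand_grid(bP = c(0.1, 0.2, 0.3), bT = c(-0.05, -0.15))
  dec <- purrr::pmap_dbl(grid, function(bP, bT) {
    mm <- hand
    mm$summary$slope_lnprecip <- bP
    mm$summary$slope_tmax <- bT
    project_growth(mm, warm, c(1900, 2000))$decline_pct
  })
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$bP[i] >= grid$bP[j] && grid$bT[i] <= grid$bT[j]) {
      expect_gte(dec[i], dec[j] - 1e-12)
    }
  }
  # missing (gcm, period) combinations are an error
  miss <- dplyr::bind_rows(hn, dplyr::mutate(hn, gcm_id = "H", period = "Q"))
  expect_error(project_growth(hand, miss), "missing normals")
})

test_that("projection distributions are compared by a two-sided t test", {
  pr <- tidyr::expand_grid(database = c("targeted", "representative"),
                           period = "P1", gcm_id = sprintf("G%02d", 1:15)) |>
    dplyr::mutate(mean_rwi = 0.5)
  expect_equal(compare_projection_distributions(pr)$p_value, 1)
  set.seed(3)
  a <- rnorm(15, 0.2, 0.1)
  b <- rnorm(15, 0.5, 0.1)   # 3 SD apart
  pr2 <- dplyr::mutate(pr, mean_rwi = c(a, b))
  res <- compare_projection_distributions(pr2)
  expect_lt(res$p_value, 0.001)
  # agrees with the Welch t reference
  expect_equal(res$p_value, stats::t.test(a, b)$p.value, tolerance = 1e-12)
  expect_error(compare_projection_distributions(pr2[c(1:2, 16:17), ]),
               "3 GCMs")
})
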