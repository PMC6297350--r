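# Regional chronology building: per-year geographic weighting, mean
# interseries correlation (rbar), variance stabilization by effective
# independent sample size, summary statistics, and the resampling envelope.

#' Geographic site weights
#'
#' Weight of each site is proportional to its mean great-circle distance to
#' all other sites in the set, so samples from sparsely collected areas
#' count more.  A single site gets weight 1; coincident sites contribute
#' distance 0 to each other; if all distances vanish, weights are equal.
#'
#' @param sites Tibble with `site_id`, `lat`, `lon`.
#' @return Tibble `site_id`, `weight`, with weights summing to 1, all
#'   strictly positive.
#' @export
geographic_weights <- function(sites) {
  stop_if_missing_cols(sites, c("site_id", "lat", "lon"), "`sites`")
  n <- nrow(sites)
  if (n < 1) stop("need at least one site")
  if (n == 1) return(tibble::tibble(site_id = sites$site_id, weight = 1))
  D <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_km(sites$lat[i], sites$lon[i], sites$lat[j], sites$lon[j])
  })
  md <- rowSums(D) / (n - 1)
  w <- if (sum(md) == 0) rep(1 / n, n) else md / sum(md)
  tibble::tibble(site_id = sites$site_id, weight = w)
}

new_chronology <- function(tbl, stabilized = FALSE) {
  structure(tbl, class = c("ring_chronology", class(tibble::tibble())),
            stabilized = stabilized)
}

#' Build a geographically weighted regional chronology
#'
#' Series are averaged to site means per year (trees -> site -> region);
#' each year's value is the weighted mean of the site means present that
#' year, with weights recomputed per year from the present sites' mean
#' distances ([geographic_weights()]).
#'
#' @param rwi Long index tibble `series_id`, `year`, `rwi`.
#' @param meta Series metadata with `series_id`, `site_id`, `lat`, `lon`.
#' @param lat_max Optional northern cutoff: only series at sites with
#'   `lat < lat_max` enter the chronology.
#' @return A `ring_chronology` tibble: `year`, `value`, `n_t` (series
#'   replication), `site_count`.
#' @export
build_regional_chronology <- function(rwi, meta, lat_max = NULL) {
  stop_if_missing_cols(rwi, c("series_id", "year", "rwi"), "`rwi`")
  stop_if_missing_cols(meta, c("series_id", "site_id", "lat", "lon"), "`meta`")
  d <- dplyr::inner_join(rwi, meta[c("series_id", "site_id", "lat", "lon")],
                         by = "series_id")
  if (!is.null(lat_max)) d <- d[d$lat < lat_max, ]
  if (!nrow(d)) stop("empty region: no series after the latitude filter")
  site_year <- d |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::summarise(site_mean = mean(.data$rwi), n = dplyr::n(),
                     .groups = "drop")
  sites <- dplyr::distinct(d, .data$site_id, .data$lat, .data$lon)
  # full pairwise distances once; per-year weights are row means of subsets
  D <- outer(seq_len(nrow(sites)), seq_len(nrow(sites)), function(i, j) {
    haversine_km(sites$lat[i], sites$lon[i], sites$lat[j], sites$lon[j])
  })
  years <- sort(unique(site_year$year))
  vals <- numeric(length(years))
  n_t <- integer(length(years))
  ns <- integer(length(years))
  for (k in seq_along(years)) {
    sy <- site_year[site_year$year == years[k], ]
    ii <- match(sy$site_id, sites$site_id)
    m <- length(ii)
    w <- if (m == 1) 1 else {
      md <- rowSums(D[ii, ii, drop = FALSE]) / (m - 1)
      if (sum(md) == 0) rep(1 / m, m) else md / sum(md)
    }
    vals[k] <- sum(w * sy$site_mean)
    n_t[k] <- sum(sy$n)
    ns[k] <- m
  }
  new_chronology(tibble::tibble(year = years, value = vals, n_t = n_t,
                                site_count = ns))
}

#' Mean interseries correlation (rbar)
#'
#' Mean Pearson correlation over all series pairs sharing at least
#' `min_overlap` common years.
#'
#' @param rwi Long index tibble `series_id`, `year`, `rwi`.
#' @param min_overlap Minimum common years per pair, default 30.
#' @return A single correlation in (-1, 1\].
#' @export
rbar <- function(rwi, min_overlap = 30) {
  stop_if_missing_cols(rwi, c("series_id", "year", "rwi"), "`rwi`")
  wide <- tidyr::pivot_wider(rwi, id_cols = "year", names_from = "series_id",
                             values_from = "rwi")
  m <- as.matrix(wide[-1])
  if (ncol(m) < 2) stop("need at least two series")
  overlap <- crossprod(!is.na(m))
  suppressWarnings(C <- cor(m, use = "pairwise.complete.obs"))
  ut <- upper.tri(C)
  ok <- ut & overlap >= min_overlap & is.finite(C)
  if (!any(ok)) stop("no series pair with at least ", min_overlap,
                     " overlapping years")
  mean(C[ok])
}

#' Variance-stabilize a chronology
#'
#' Replication-driven variance inflation is removed by scaling deviations
#' from the chronology mean by the square root of the effective independent
#' sample size, `n_eff(t) = n_t / (1 + (n_t - 1) * rbar)`, rescaled so the
#' variance over the maximum-replication years is unchanged; the mean is
#' preserved exactly.  A second call on an already-stabilized chronology is
#' a no-op; `rbar <= 0` leaves the input untouched with a warning
#' (stabilization undefined).
#'
#' @param chron A `ring_chronology`.
#' @param rbar Mean interseries correlation in (0, 1).
#' @return The stabilized `ring_chronology`.
#' @export
variance_stabilize <- function(chron, rbar) {
  stop_if_missing_cols(chron, c("year", "value", "n_t"), "`chron`")
  if (isTRUE(attr(chron, "stabilized"))) return(chron)
  if (rbar <= 0) {
    warning("rbar <= 0: variance stabilization undefined, returning input")
    return(chron)
  }
  if (rbar >= 1) stop("rbar must lie in (0, 1)")
  neff <- chron$n_t / (1 + (chron$n_t - 1) * rbar)
  scale <- sqrt(neff / max(neff))
  mu <- mean(chron$value)
  v <- mu + (chron$value - mu) * scale
  out <- chron
  out$value <- v - mean(v) + mu
  new_chronology(tibble::as_tibble(out), stabilized = TRUE)
}

#' Chronology summary statistics
#'
#' Sample SD, lag-1 autocorrelation, and lag-2 partial autocorrelation
#' (Durbin-Levinson recursion, via [stats::pacf()]).
#'
#' @param chron A `ring_chronology` (or tibble with `year`, `value`).
#' @param window Optional year window `c(lo, hi)`.
#' @return One-row tibble `sd`, `acf1`, `pacf2`, `n_years`.
#' @export
chronology_stats <- function(chron, window = NULL) {
  x <- chron$value
  if (!is.null(window)) {
    x <- x[chron$year >= window[1] & chron$year <= window[2]]
  }
  if (length(x) < 10) stop("window shorter than 10 years")
  a <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  p <- stats::pacf(x, lag.max = 2, plot = FALSE)$acf[2]
  tibble::tibble(sd = sd(x), acf1 = a, pacf2 = p, n_years = length(x))
}

#' Resampling envelope of a regional chronology
#'
#' Repeatedly draws `target_n` series without replacement from the pool,
#' rebuilds the chronology, and records the per-year spread across
#' replicates, quantifying how much of a chronology's character is due to
#' which trees happened to be sampled.
#'
#' @param rwi Long index tibble.
#' @param meta Series metadata (as in [build_regional_chronology()]).
#' @param target_n Series per replicate; at most the pool size.
#' @param replicates Number of replicates, default 100.
#' @param seed Optional integer seed.
#' @param lat_max Optional northern cutoff applied before pooling.
#' @return Tibble `year`, `lo`, `hi`, `sd`, `n_replicates` (per-year
#'   replicate coverage).
#' @export
resample_envelope <- function(rwi, meta, target_n, replicates = 100,
                              seed = NULL, lat_max = NULL) {
  if (!is.null(lat_max)) {
    keep <- meta$series_id[meta$lat < lat_max]
    rwi <- rwi[rwi$series_id %in% keep, ]
  }
  pool <- unique(rwi$series_id)
  if (target_n > length(pool)) {
    stop("target_n exceeds the pool size (", length(pool), ")")
  }
  with_seed(seed, {
    reps <- lapply(seq_len(replicates), function(r) {
      ids <- pool[sample.int(length(pool), target_n)]
      ch <- build_regional_chronology(rwi[rwi$series_id %in% ids, ], meta)
      tibble::tibble(replicate = r, year = ch$year, value = ch$value)
    })
    dplyr::bind_rows(reps) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(lo = min(.data$value), hi = max(.data$value),
                       sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                       n_replicates = dplyr::n(), .groups = "drop")
  })
}
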