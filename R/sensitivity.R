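# Per-tree growth variability and climate sensitivity over the fixed
# analysis window: seasonal predictor construction, in-window SD, and the
# three-predictor multiple regression.

#' Seasonal climate predictors from monthly records
#'
#' For each site and year Y builds the three predictors of ring-width
#' variation in the semi-arid Southwest: total cool-season precipitation
#' (November of Y-1 through March of Y), mean maximum temperature of the
#' prior fall (August-October of Y-1) and of the current summer (May-July
#' of Y).  A year is emitted only if every contributing month is present;
#' the first year of a record is therefore always omitted.
#'
#' @param climate Monthly tibble with `site_id`, `year`, `month`,
#'   `precip_mm`, `tmax_C`.
#' @return Tibble `site_id`, `year`, `precip_cool`, `tmax_fall_prev`,
#'   `tmax_summer`.
#' @export
seasonal_predictors <- function(climate) {
  stop_if_missing_cols(climate, c("site_id", "year", "month", "precip_mm",
                                  "tmax_C"), "`climate`")
  cool <- climate |>
    dplyr::mutate(target = dplyr::case_when(
      .data$month >= 11 ~ .data$year + 1L,
      .data$month <= 3 ~ .data$year,
      TRUE ~ NA_integer_
    )) |>
    dplyr::filter(!is.na(.data$target)) |>
    dplyr::group_by(.data$site_id, year = .data$target) |>
    dplyr::summarise(precip_cool = sum(.data$precip_mm), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n == 5L) |>
    dplyr::select(-"n")
  fall <- climate |>
    dplyr::filter(.data$month %in% 8:10) |>
    dplyr::group_by(.data$site_id, year = .data$year + 1L) |>
    dplyr::summarise(tmax_fall_prev = mean(.data$tmax_C), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n == 3L) |>
    dplyr::select(-"n")
  summer <- climate |>
    dplyr::filter(.data$month %in% 5:7) |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::summarise(tmax_summer = mean(.data$tmax_C), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n == 3L) |>
    dplyr::select(-"n")
  cool |>
    dplyr::inner_join(fall, by = c("site_id", "year")) |>
    dplyr::inner_join(summer, by = c("site_id", "year")) |>
    dplyr::arrange(.data$site_id, .data$year)
}

#' In-window standard deviation of a ring-width index series
#'
#' Sample SD (n-1 denominator) over the years falling inside the analysis
#' window.  Series with fewer than 30 in-window years are excluded: the
#' function returns `NA`, the exclusion signal, rather than a number.
#'
#' @param rwi Index values.
#' @param years Matching calendar years.
#' @param window Analysis window, default 1930-1995.
#' @param min_overlap Minimum in-window years (default 30).
#' @return Sample SD, or `NA_real_` when excluded.
#' @export
series_sd <- function(rwi, years, window = c(1930, 1995), min_overlap = 30) {
  inw <- years >= window[1] & years <= window[2] & !is.na(rwi)
  if (sum(inw) < min_overlap) return(NA_real_)
  sd(rwi[inw])
}

#' Per-series climate-sensitivity regression
#'
#' Ordinary least squares of the ring-width index on the three seasonal
#' predictors, each z-scored over the series' own in-window years, with an
#' intercept.  Slopes are therefore in index units per predictor SD and
#' comparable across trees.
#'
#' @param data Tibble for one series with columns `year`, `rwi`,
#'   `precip_cool`, `tmax_fall_prev`, `tmax_summer`.
#' @param window Analysis window, default 1930-1995.
#' @param min_overlap Minimum complete in-window years (default 30).
#' @return One-row tibble `beta_precip`, `beta_fallT`, `beta_summerT`,
#'   `r2`, `n_years`.
#' @export
climate_regression <- function(data, window = c(1930, 1995),
                               min_overlap = 30) {
  stop_if_missing_cols(data, c("year", "rwi", "precip_cool", "tmax_fall_prev",
                               "tmax_summer"), "`data`")
  d <- data[data$year >= window[1] & data$year <= window[2], ]
  d <- d[complete.cases(d[c("rwi", "precip_cool", "tmax_fall_prev",
                            "tmax_summer")]), ]
  if (nrow(d) < min_overlap) {
    stop("fewer than ", min_overlap, " overlapping years in the window")
  }
  preds <- c("precip_cool", "tmax_fall_prev", "tmax_summer")
  Z <- vapply(preds, function(p) {
    s <- sd(d[[p]])
    if (s == 0) stop("constant predictor in window: ", p)
    (d[[p]] - mean(d[[p]])) / s
  }, numeric(nrow(d)))
  if (qr(cbind(1, Z))$rank < 4L) {
    stop("singular design: collinear predictors")
  }
  fit <- lm(d$rwi ~ Z)
  tibble::tibble(
    beta_precip = coef(fit)[[2]],
    beta_fallT = coef(fit)[[3]],
    beta_summerT = coef(fit)[[4]],
    r2 = summary(fit)$r.squared,
    n_years = nrow(d)
  )
}

#' Tree-level sensitivity table
#'
#' One record per retained series: in-window SD, the three standardized
#' regression slopes and R2, age (mean cumulative ring count in the window,
#' counted from the innermost ring or from `pith_year` when the metadata
#' provides it) and site attributes.  Series with insufficient window
#' overlap are excluded and logged in the `"exclusions"` attribute.
#'
#' @param rwi Long index tibble `series_id`, `year`, `rwi`.
#' @param climate Seasonal predictor table (from [seasonal_predictors()]),
#'   or a monthly climate table, which is aggregated first.
#' @param meta Series metadata: `series_id`, `site_id`, and any of `lat`,
#'   `lon`, `elev_m`, `species`, `database`, `pith_year`.
#' @param window Analysis window, default 1930-1995.
#' @param min_overlap Minimum in-window years (default 30).
#' @return Sensitivity tibble; attribute `exclusions` lists dropped series
#'   with reasons.
#' @export
build_sensitivity_table <- function(rwi, climate, meta,
                                    window = c(1930, 1995),
                                    min_overlap = 30) {
  stop_if_missing_cols(rwi, c("series_id", "year", "rwi"), "`rwi`")
  stop_if_missing_cols(meta, c("series_id", "site_id"), "`meta`")
  if ("month" %in% names(climate)) climate <- seasonal_predictors(climate)
  keep <- intersect(c("series_id", "site_id", "lat", "lon", "elev_m",
                      "species", "database", "pith_year"), names(meta))
  meta <- meta[keep]
  joined <- rwi |>
    dplyr::inner_join(meta, by = "series_id") |>
    dplyr::inner_join(climate, by = c("site_id", "year"))
  pieces <- split(joined, joined$series_id)
  rows <- vector("list", length(pieces))
  excl <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    d <- pieces[[i]]
    id <- d$series_id[1]
    s <- series_sd(d$rwi, d$year, window, min_overlap)
    if (is.na(s)) {
      excl[[i]] <- tibble::tibble(series_id = id,
                                  reason = "window overlap below minimum")
      next
    }
    reg <- climate_regression(d, window, min_overlap)
    pith <- if ("pith_year" %in% names(d)) d$pith_year[1] else min(d$year)
    inw <- d$year >= window[1] & d$year <= window[2]
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(series_id = id, sd = s,
                     age = mean(d$year[inw] - pith + 1)),
      reg,
      d[1, setdiff(keep, c("series_id", "pith_year")), drop = FALSE]
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- dplyr::bind_rows(excl)
  out
}
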