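# Regional climate-growth model with a database contrast, projection under
# future climate normals, and the headline percent arithmetic.

#' Fit the regional climate-growth model
#'
#' A single OLS fit with database-interaction structure — equivalent to two
#' per-database regressions of the chronology on standardized ln(cool-season
#' precipitation) and standardized dry-season maximum temperature (the
#' average of the prior-fall and current-summer series), with intercepts.
#' Predictors are standardized over the calibration window; slopes are in
#' index units per predictor SD.
#'
#' @param chron_targeted,chron_representative `ring_chronology` tibbles.
#' @param climate Regional seasonal climate: `year`, `precip_cool`,
#'   `tmax_fall_prev`, `tmax_summer`.
#' @param window Calibration window, default 1902-2008.
#' @return A `regional_model` object; see [tidy.regional_model()] and
#'   [glance.regional_model()].
#' @export
fit_regional_model <- function(chron_targeted, chron_representative, climate,
                               window = c(1902, 2008)) {
  stop_if_missing_cols(climate, c("year", "precip_cool", "tmax_fall_prev",
                                  "tmax_summer"), "`climate`")
  clim <- climate[climate$year >= window[1] & climate$year <= window[2], ]
  if (any(clim$precip_cool <= 0)) {
    stop("non-positive precipitation in the calibration window: cannot log")
  }
  clim$lnp <- log(clim$precip_cool)
  clim$tmax <- (clim$tmax_fall_prev + clim$tmax_summer) / 2
  stack <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(chron_targeted), database = "targeted"),
    dplyr::mutate(tibble::as_tibble(chron_representative),
                  database = "representative")
  ) |>
    dplyr::inner_join(clim[c("year", "lnp", "tmax")], by = "year")
  n_yr <- stack |>
    dplyr::count(.data$database)
  if (nrow(n_yr) < 2 || any(n_yr$n < 30)) {
    stop("calibration window overlap below 30 years")
  }
  scaling <- list(mean_lnp = mean(clim$lnp), sd_lnp = sd(clim$lnp),
                  mean_tmax = mean(clim$tmax), sd_tmax = sd(clim$tmax))
  stack$zlnp <- (stack$lnp - scaling$mean_lnp) / scaling$sd_lnp
  stack$ztmax <- (stack$tmax - scaling$mean_tmax) / scaling$sd_tmax
  stack$database <- factor(stack$database,
                           levels = c("targeted", "representative"))
  fit <- lm(value ~ 0 + database + database:zlnp + database:ztmax,
            data = stack)
  per_db <- lapply(levels(stack$database), function(db) {
    f <- lm(value ~ zlnp + ztmax, data = stack[stack$database == db, ])
    sm <- summary(f)
    tibble::tibble(database = db,
                   slope_lnprecip = coef(f)[["zlnp"]],
                   slope_tmax = coef(f)[["ztmax"]],
                   r2_adj = sm$adj.r.squared,
                   sigma = sm$sigma,
                   n_years = sum(stack$database == db))
  })
  structure(list(fit = fit, summary = dplyr::bind_rows(per_db),
                 scaling = scaling, window = window, data = stack),
            class = "regional_model")
}

#' @export
print.regional_model <- function(x, ...) {
  cat("Regional climate-growth model (calibration ",
      x$window[1], "-", x$window[2], ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy a regional climate-growth model
#'
#' @param x A `regional_model`.
#' @param ... Unused.
#' @return One row per database and term with estimate, standard error,
#'   statistic and p-value.
#' @method tidy regional_model
#' @export
tidy.regional_model <- function(x, ...) {
  dbs <- levels(x$data$database)
  purrr::map_dfr(dbs, function(db) {
    f <- lm(value ~ zlnp + ztmax, data = x$data[x$data$database == db, ])
    cf <- summary(f)$coefficients
    tibble::tibble(database = db,
                   term = c("(Intercept)", "z_ln_precip", "z_tmax"),
                   estimate = cf[, 1], std.error = cf[, 2],
                   statistic = cf[, 3], p.value = cf[, 4])
  })
}

#' Model-level summary of a regional climate-growth model
#'
#' @param x A `regional_model`.
#' @param ... Unused.
#' @return One row per database: slopes, adjusted R2, residual sigma, n.
#' @method glance regional_model
#' @export
glance.regional_model <- function(x, ...) {
  x$summary
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

infer_decimals <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  has <- grepl(".", s, fixed = TRUE)
  ifelse(has, nchar(sub(".*\\.", "", s)), 0L)
}

#' Percent contrast between two sensitivity slopes
#'
#' `100 * (slope_targeted - slope_representative) / slope_representative`.
#' When `rounded = TRUE` (default) the difference is first rounded to the
#' precision of the inputs — reproducing arithmetic done on printed
#' coefficients — and the result is reported to the nearest integer
#' percent; the rounded difference is attached as attribute `"difference"`.
#'
#' @param slope_targeted,slope_representative Slopes; the representative
#'   slope must be nonzero.
#' @param rounded Reproduce printed-precision arithmetic (default) or
#'   return the raw percentage.
#' @return Percent steepness of the targeted slope over the representative.
#' @examples
#' sensitivity_contrast_pct(0.161, 0.101) # 59
#' @export
sensitivity_contrast_pct <- function(slope_targeted, slope_representative,
                                     rounded = TRUE) {
  if (slope_representative == 0) stop("representative slope is zero")
  if (!rounded) {
    return(100 * (slope_targeted - slope_representative) /
             slope_representative)
  }
  digits <- max(infer_decimals(slope_targeted),
                infer_decimals(slope_representative))
  diff <- round(slope_targeted - slope_representative, digits)
  structure(round(100 * diff / slope_representative), difference = diff)
}

#' Contrast between two projected growth declines
#'
#' Given positive percent declines for the targeted and representative
#' projections, returns how much *less* decline the representative
#' projection shows relative to the targeted one, and how much *stronger*
#' the targeted reduction is relative to the representative one, both to
#' the nearest integer percent.
#'
#' @param decline_targeted_pct,decline_representative_pct Positive percent
#'   declines.
#' @return One-row tibble `less_decline_pct`, `stronger_reduction_pct`.
#' @examples
#' decline_contrast(106, 75) # 29 and 41
#' @export
decline_contrast <- function(decline_targeted_pct,
                             decline_representative_pct) {
  if (decline_targeted_pct <= 0 || decline_representative_pct <= 0) {
    stop("both declines must be positive")
  }
  d <- decline_targeted_pct - decline_representative_pct
  tibble::tibble(
    less_decline_pct = round(100 * d / decline_targeted_pct),
    stronger_reduction_pct = round(100 * d / decline_representative_pct)
  )
}

#' Project regional growth under future climate normals
#'
#' Applies the fitted standardized slopes to each normal's anomalies:
#' the precipitation anomaly is `ln(precip_factor)` over the
#' calibration-window SD of ln precipitation, the temperature anomaly is
#' `delta_tmax` over the calibration-window SD of the dry-season
#' temperature.  Projections are anchored at the baseline-window mean of
#' the observed chronology, so null normals (no warming, factor 1) give
#' exactly zero decline.  The projected index is a linear extrapolation and
#' may be negative; `decline_pct` then exceeds 100.
#'
#' @param model A `regional_model`.
#' @param normals Future normals tibble: `gcm_id`, `period`, `delta_tmax`,
#'   `precip_factor` (one record per gcm and period).
#' @param baseline Baseline window (twentieth-century mean), default
#'   1902-1999.
#' @return A `ring_projection` tibble: one row per (database, period, gcm)
#'   with `mean_rwi` and `decline_pct`.
#' @export
project_growth <- function(model, normals, baseline = c(1902, 1999)) {
  stopifnot(inherits(model, "regional_model"))
  stop_if_missing_cols(normals, c("gcm_id", "period", "delta_tmax",
                                  "precip_factor"), "`normals`")
  if (any(normals$precip_factor <= 0)) stop("precip_factor must be positive")
  if (anyDuplicated(normals[c("gcm_id", "period")])) {
    stop("duplicate (gcm_id, period) record")
  }
  full <- tidyr::expand_grid(gcm_id = unique(normals$gcm_id),
                             period = unique(normals$period))
  miss <- dplyr::anti_join(full, normals, by = c("gcm_id", "period"))
  if (nrow(miss)) {
    stop("missing normals for ", miss$gcm_id[1], " / ", miss$period[1])
  }
  out <- purrr::map_dfr(unique(model$data$database), function(db) {
    d <- model$data[model$data$database == db, ]
    base <- d$value[d$year >= baseline[1] & d$year <= baseline[2]]
    if (!length(base)) stop("baseline window outside the calibration data")
    base_mean <- mean(base)
    sl <- model$summary[model$summary$database == db, ]
    zp <- log(normals$precip_factor) / model$scaling$sd_lnp
    zt <- normals$delta_tmax / model$scaling$sd_tmax
    mean_rwi <- base_mean + sl$slope_lnprecip * zp + sl$slope_tmax * zt
    tibble::tibble(database = db, period = normals$period,
                   gcm_id = normals$gcm_id,
                   scenario = if ("scenario" %in% names(normals))
                     normals$scenario else NA_character_,
                   mean_rwi = mean_rwi,
                   decline_pct = 100 * (base_mean - mean_rwi) / base_mean)
  })
  structure(out, class = c("ring_projection", class(out)))
}

#' Compare projected growth between databases
#'
#' Two-sided t test across GCMs, per period, of the projected mean
#' ring-width index of the targeted vs representative model.
#'
#' @param results A `ring_projection` table from [project_growth()].
#' @return Tibble per period: group means, t statistic, p-value.
#' @export
compare_projection_distributions <- function(results) {
  stop_if_missing_cols(results, c("database", "period", "gcm_id", "mean_rwi"),
                       "`results`")
  purrr::map_dfr(unique(results$period), function(p) {
    a <- results$mean_rwi[results$period == p &
                            results$database == "targeted"]
    b <- results$mean_rwi[results$period == p &
                            results$database == "representative"]
    if (length(a) < 3 || length(b) < 3) {
      stop("need at least 3 GCMs per database and period")
    }
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble::tibble(period = p, mean_targeted = mean(a),
                            mean_representative = mean(b),
                            statistic = 0,
                            p_value = if (mean(a) == mean(b)) 1 else 0))
    }
    tt <- stats::t.test(a, b)
    tibble::tibble(period = p, mean_targeted = mean(a),
                   mean_representative = mean(b),
                   statistic = unname(tt$statistic),
                   p_value = tt$p.value)
  })
}
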