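# Conversion of raw ring widths to ring-width index (RWI): the classic
# conservative modified negative exponential, frequency-cutoff smoothing
# splines, ratio detrending, and optional AR prewhitening.

#' Fit a modified negative exponential growth curve
#'
#' Fits `a * exp(-b * t) + k` (t = 1..n, ring index from the innermost ring)
#' with `a > 0`, `b > 0`, `k >= 0` by Levenberg-Marquardt least squares.
#' When the nonlinear fit fails ("poor fit": non-convergence, invalid
#' parameters, or a non-positive curve) a least-squares straight line is
#' substituted; if that line's slope is non-negative, the horizontal mean
#' line is used (nonincreasing convention).  A valid input never raises:
#' the fallback guarantees a curve.
#'
#' @param widths Numeric vector of raw ring widths (mm), at least 10 rings.
#' @return A list with `curve` (fitted values, strictly positive), `params`
#'   (named `a`, `b`, `k`, or `NULL` on fallback) and `fallback` (one of
#'   `"none"`, `"line"`, `"mean"`).
#' @export
fit_modified_negexp <- function(widths) {
  n <- length(widths)
  if (n < 10) stop("need at least 10 rings to fit a growth curve")
  if (any(!is.finite(widths)) || any(widths <= 0)) {
    stop("ring widths must be positive and finite")
  }
  t <- seq_len(n)
  k0 <- max(0.8 * min(widths), 1e-4)
  a0 <- max(mean(widths[seq_len(max(3L, n %/% 10))]) - k0, 1e-3)
  # slope of log residual growth gives a starting decay rate
  lw <- log(pmax(widths - k0, 1e-6))
  b0 <- max(-coef(lm(lw ~ t))[[2]], 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      widths ~ a * exp(-b * t) + k,
      start = list(a = a0, b = b0, k = k0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- coef(fit)
    curve <- p[["a"]] * exp(-p[["b"]] * t) + p[["k"]]
    if (p[["a"]] > 0 && p[["b"]] > 0 && p[["k"]] >= 0 && all(curve > 0)) {
      return(list(curve = as.numeric(curve),
                  params = c(a = p[["a"]], b = p[["b"]], k = p[["k"]]),
                  fallback = "none"))
    }
  }
  line <- lm(widths ~ t)
  if (coef(line)[[2]] < 0) {
    curve <- as.numeric(stats::fitted(line))
    if (all(curve > 0)) {
      return(list(curve = curve, params = NULL, fallback = "line"))
    }
  }
  list(curve = rep(mean(widths), n), params = NULL, fallback = "mean")
}

#' Ratio detrending
#'
#' Divides ring widths by a fitted growth curve, yielding a dimensionless
#' ring-width index with mean near 1.
#'
#' @param widths Raw ring widths.
#' @param curve Fitted curve of the same length, strictly positive.
#' @return Numeric RWI vector.
#' @export
detrend_ratio <- function(widths, curve) {
  if (length(widths) != length(curve)) {
    stop("`widths` and `curve` must have the same length")
  }
  if (any(curve <= 0)) stop("growth curve must be strictly positive")
  widths / curve
}

#' Frequency-cutoff smoothing spline
#'
#' A discrete penalized (second-difference) smoothing spline whose stiffness
#' is solved from the 50% frequency-cutoff criterion: the amplitude response
#' of the smoother equals 0.50 at wavelength `cutoff_years` and exceeds 0.95
#' at wavelengths of 10 times the cutoff.  The series is padded by point
#' reflection at both ends before solving to suppress boundary leakage,
#' then cropped.
#'
#' @param y Numeric series.
#' @param cutoff_years Wavelength (years) at which amplitude is halved;
#'   must be positive, and the series must be longer than `cutoff_years / 2`.
#' @return The smooth curve, clipped below at 0.001 so it can serve as a
#'   ratio-detrending divisor.
#' @export
smoothing_spline <- function(y, cutoff_years) {
  if (cutoff_years <= 0) stop("`cutoff_years` must be positive")
  n0 <- length(y)
  if (n0 <= cutoff_years / 2) {
    stop("series too short for a ", cutoff_years, "-year cutoff")
  }
  if (any(!is.finite(y))) stop("series must be finite")
  pad <- min(n0 - 1L, 2L * as.integer(ceiling(cutoff_years)))
  yy <- c(2 * y[1] - y[seq(pad + 1L, 2L)],
          y,
          2 * y[n0] - y[seq(n0 - 1L, n0 - pad)])
  n <- length(yy)
  lambda <- 1 / (16 * sin(pi / cutoff_years)^4)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2, diagonals = list(
    rep(1, n - 2L), rep(-2, n - 2L), rep(1, n - 2L)
  ))
  z <- as.numeric(Matrix::solve(Matrix::Diagonal(n) + lambda * Matrix::crossprod(D),
                                yy))
  pmax(z[seq(pad + 1L, pad + n0)], 0.001)
}

#' Remove temporal autocorrelation from an index series
#'
#' Fits an autoregressive model with AIC-selected order (0..`order_max`)
#' and returns the residuals re-centred on the input mean, so the output
#' remains an index near 1.  The leading `order` values, undefined for the
#' AR residual, are dropped.
#'
#' @param x Numeric index series of at least 30 values.
#' @param order_max Maximum AR order considered (default 10).
#' @return A list with `index` (residual series, length `length(x) - order`),
#'   `order` (selected AR order) and `zero_variance` flag.
#' @export
prewhiten <- function(x, order_max = 10) {
  n <- length(x)
  if (n < 30) stop("prewhitening needs at least 30 values")
  if (sd(x) == 0) {
    return(list(index = x, order = 0L, zero_variance = TRUE))
  }
  fit <- stats::ar(x, aic = TRUE, order.max = order_max, method = "yule-walker")
  p <- fit$order
  if (p == 0L) {
    return(list(index = x, order = 0L, zero_variance = FALSE))
  }
  res <- fit$resid[!is.na(fit$resid)]
  list(index = res - mean(res) + mean(x), order = as.integer(p),
       zero_variance = FALSE)
}

#' Detrend a ring-width collection
#'
#' Applies one of the three detrending options to every series of a long
#' ring-width table and returns the ring-width index.  Per-series fitting
#' detail (fallback used, AR order) is attached as the `"detrend_info"`
#' attribute; series shorter than 10 rings (or than half the spline cutoff,
#' for the spline methods) are excluded and logged there.
#'
#' @param rw Tibble with columns `series_id`, `year`, `width_mm`.
#' @param method `"negexp"` (modified negative exponential with line/mean
#'   fallback), `"spline30"` or `"spline100"` (smoothing spline with a 50%
#'   frequency cutoff at 30 or 100 years).
#' @param prewhiten Remove AR autocorrelation from each index series?
#'   Series shorter than 30 years are left unwhitened.
#' @param floor_mm Growth-curve floor (mm) applied before division, guarding
#'   against index blow-ups over near-zero fitted values.
#' @return Tibble with columns `series_id`, `year`, `rwi`; attribute
#'   `detrend_info` holds one row per input series.
#' @export
detrend <- function(rw, method = c("negexp", "spline30", "spline100"),
                    prewhiten = FALSE, floor_mm = 0.001) {
  method <- match.arg(method)
  stop_if_missing_cols(rw, c("series_id", "year", "width_mm"), "`rw`")
  pieces <- split(rw[order(rw$series_id, rw$year), ], rw$series_id[order(rw$series_id, rw$year)])
  info <- vector("list", length(pieces))
  out <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    d <- pieces[[i]]
    id <- d$series_id[1]
    if (nrow(d) < 10) {
      info[[i]] <- tibble::tibble(series_id = id, method = method,
                                  fallback = NA_character_, ar_order = NA_integer_,
                                  excluded = "fewer than 10 rings")
      next
    }
    w <- d$width_mm
    if (method == "negexp") {
      f <- fit_modified_negexp(w)
      curve <- f$curve
      fb <- f$fallback
    } else {
      cutoff <- if (method == "spline30") 30 else 100
      if (nrow(d) <= cutoff / 2) {
        info[[i]] <- tibble::tibble(series_id = id, method = method,
                                    fallback = NA_character_,
                                    ar_order = NA_integer_,
                                    excluded = paste0("shorter than cutoff/2 (",
                                                      cutoff / 2, " years)"))
        next
      }
      curve <- smoothing_spline(w, cutoff)
      fb <- "none"
    }
    rwi <- detrend_ratio(w, pmax(curve, floor_mm))
    yrs <- d$year
    ord <- 0L
    if (isTRUE(prewhiten) && length(rwi) >= 30) {
      pw <- prewhiten(rwi)
      ord <- pw$order
      rwi <- pw$index
      yrs <- yrs[(length(yrs) - length(rwi) + 1L):length(yrs)]
    }
    out[[i]] <- tibble::tibble(series_id = id, year = yrs, rwi = rwi)
    info[[i]] <- tibble::tibble(series_id = id, method = method, fallback = fb,
                                ar_order = ord, excluded = NA_character_)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "detrend_info") <- dplyr::bind_rows(info)
  res
}
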