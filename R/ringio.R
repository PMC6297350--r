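# Tucson decadal (.rwl) ring-width archives and the CSV side tables.
# Internal width unit is always mm; the 0.01 / 0.001 mm integer encodings
# exist only at the file boundary.

#' Read a Tucson decadal ring-width file
#'
#' Parses a `.rwl` archive into a long tibble of dated ring widths.  Decadal
#' rows are reassembled into contiguous yearly vectors; the terminator value
#' is excluded and resolves the measurement unit (`999` = 0.01 mm, `-9999` =
#' 0.001 mm).  Malformed input is rejected, never repaired: non-contiguous or
#' duplicated years within a series are errors naming the series and year.
#'
#' @param path Path to an existing `.rwl` file.
#' @return A tibble with columns `series_id`, `year`, `width_mm`.
#' @seealso [write_rwl()]
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty .rwl file: ", path)
  ids <- trimws(substr(lines, 1L, 8L))
  body <- substring(lines, 9L)
  parsed <- lapply(body, function(x) {
    scan(text = x, what = numeric(), quiet = TRUE)
  })
  short <- lengths(parsed) < 2L
  if (any(short)) {
    stop("malformed .rwl row (need a year and at least one value): ",
         lines[which(short)[1]])
  }
  rows_by_series <- split(seq_along(lines), factor(ids, levels = unique(ids)))
  out <- lapply(names(rows_by_series), function(id) {
    idx <- rows_by_series[[id]]
    yr_all <- integer(0)
    v_all <- numeric(0)
    for (j in idx) {
      vals <- parsed[[j]][-1L]
      yrs <- parsed[[j]][1L] + seq_along(vals) - 1
      yr_all <- c(yr_all, as.integer(yrs))
      v_all <- c(v_all, vals)
    }
    nv <- length(v_all)
    term <- v_all[nv]
    if (!term %in% c(999, -9999)) {
      stop("series '", id, "': missing terminator (999 or -9999)")
    }
    divisor <- if (term == 999) 100 else 1000
    v_all <- v_all[-nv]
    yr_all <- yr_all[-nv]
    if (!length(v_all)) stop("series '", id, "': no data values")
    if (anyDuplicated(yr_all)) {
      stop("series '", id, "': duplicate year ",
           yr_all[duplicated(yr_all)][1], " (overlapping decade rows)")
    }
    if (length(yr_all) > 1 && any(diff(yr_all) != 1)) {
      at <- yr_all[which(diff(yr_all) != 1)[1]]
      stop("series '", id, "': non-contiguous years after ", at)
    }
    if (any(v_all <= 0)) {
      stop("series '", id, "': non-positive ring width at year ",
           yr_all[which(v_all <= 0)[1]])
    }
    tibble::tibble(series_id = id, year = yr_all, width_mm = v_all / divisor)
  })
  dplyr::bind_rows(out)
}

#' Write a Tucson decadal ring-width file
#'
#' Inverse of [read_rwl()]: `read_rwl(write_rwl(x, path))` reproduces `x`
#' at the chosen precision.  Precision 0.001 mm uses the `-9999` terminator,
#' 0.01 mm uses `999`.
#'
#' @param rw Tibble with columns `series_id` (max 8 characters), `year`,
#'   `width_mm`; years must be contiguous within each series.
#' @param path Output path.
#' @param precision Measurement unit written to file, 0.001 (default) or
#'   0.01 mm.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rw, path, precision = 0.001) {
  stop_if_missing_cols(rw, c("series_id", "year", "width_mm"), "`rw`")
  if (nrow(rw) == 0) stop("empty collection: nothing to write")
  if (!isTRUE(precision %in% c(0.001, 0.01))) {
    stop("`precision` must be 0.001 or 0.01 (mm)")
  }
  ids <- unique(rw$series_id)
  too_long <- ids[nchar(ids) > 8]
  if (length(too_long)) {
    stop("series_id longer than 8 characters: ", too_long[1])
  }
  term <- if (precision == 0.001) -9999L else 999L
  lines <- character(0)
  for (id in ids) {
    d <- rw[rw$series_id == id, ]
    d <- d[order(d$year), ]
    if (nrow(d) > 1 && any(diff(d$year) != 1)) {
      stop("series '", id, "': years not contiguous")
    }
    vals <- c(as.integer(round(d$width_mm / precision)), term)
    yrs <- c(d$year, d$year[nrow(d)] + 1L)
    starts <- yrs %% 10 == 0
    starts[1] <- TRUE
    grp <- cumsum(starts)
    for (g in unique(grp)) {
      sel <- grp == g
      lines <- c(lines, paste0(
        sprintf("%-8s%4d", id, yrs[sel][1]),
        paste(sprintf("%6d", vals[sel]), collapse = "")
      ))
    }
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a monthly climate CSV
#'
#' Expects columns `site_id`, `year`, `month`, `precip_mm`, `tmax_C`.
#' The calendar is validated; months missing within each site's observed
#' year span are flagged in the `"gaps"` attribute, never imputed.
#'
#' @param path Path to a CSV file.
#' @return A tibble of monthly records with attribute `gaps`, a tibble of
#'   `(site_id, year, month)` combinations absent from the file.
#' @export
read_climate_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    year = readr::col_integer(),
    month = readr::col_integer(),
    precip_mm = readr::col_double(),
    tmax_C = readr::col_double()
  ))
  stop_if_missing_cols(x, c("site_id", "year", "month", "precip_mm", "tmax_C"),
                       "climate file")
  if (any(x$month < 1 | x$month > 12, na.rm = TRUE)) {
    stop("month outside 1..12")
  }
  if (any(x$precip_mm < 0, na.rm = TRUE)) stop("negative precipitation")
  if (any(!is.finite(x$tmax_C))) stop("non-finite temperature")
  if (anyDuplicated(x[c("site_id", "year", "month")])) {
    stop("duplicate (site, year, month) record")
  }
  grid <- x |>
    dplyr::group_by(.data$site_id) |>
    dplyr::reframe(year = rep(seq(min(.data$year), max(.data$year)), each = 12),
                   month = rep(1:12, max(.data$year) - min(.data$year) + 1))
  gaps <- dplyr::anti_join(grid, x, by = c("site_id", "year", "month"))
  attr(x, "gaps") <- gaps
  x
}
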