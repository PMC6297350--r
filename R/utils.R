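#' @importFrom rlang %||% .data
#' @importFrom stats median sd cor lm coef pnorm rnorm runif rlnorm rpois
#'   quantile complete.cases
NULL

# Evaluate `code` with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched. seed = NULL runs `code` on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2 || anyNA(x) || x[1] > x[2]) {
    stop("`", name, "` must be a non-empty numeric range c(lo, hi)", call. = FALSE)
  }
  x
}

stop_if_missing_cols <- function(data, cols, what) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km, the conventional Earth
#' radius used for site neighborhood searches.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees; vectors are
#'   recycled pairwise.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1) # ~111.2 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude out of range [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180)) stop("longitude out of range [-180, 180]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}
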