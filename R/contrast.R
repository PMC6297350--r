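# Geographically local comparison of targeted vs representative sensitivity
# statistics: 100 km neighborhoods, bootstrapped two-sided Wilcoxon tests,
# and the per-site median contrasts.

# Two-sided rank-sum p-value, normal approximation with tie correction.
# Kept internal and minimal: the bootstrap calls it ~10^6 times.
ranksum_p <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  tl <- rle(sort(r))$lengths
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tl^3 - tl) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  2 * pnorm(-abs((W - n1 * (N + 1) / 2) / sqrt(sig2)))
}

#' Bootstrapped two-sided Wilcoxon rank-sum test
#'
#' Controls for unequal group sizes: in each iteration the larger group is
#' subsampled without replacement to the smaller group's size and a
#' two-sided rank-sum test (normal approximation, tie-corrected) is run;
#' the returned p-value is the median over iterations.  When the groups are
#' equal-sized the subsample is the whole group, every iteration is
#' identical, and the single exact value is returned.  Groups smaller than
#' 3 fall back, with a warning, to the exact rank-sum test.
#'
#' @param a,b Numeric value groups (non-empty).
#' @param iterations Bootstrap iterations, default 1000.
#' @param seed Optional integer seed; the global RNG stream is untouched.
#' @return A p-value in \[0, 1\].
#' @export
bootstrap_wilcoxon <- function(a, b, iterations = 1000, seed = NULL) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (min(length(a), length(b)) < 3) {
    warning("group smaller than 3: falling back to the exact rank-sum test")
    return(stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
  if (length(a) == length(b)) return(ranksum_p(a, b))
  small <- if (length(a) < length(b)) a else b
  big <- if (length(a) < length(b)) b else a
  ns <- length(small)
  with_seed(seed, {
    ps <- vapply(seq_len(iterations), function(i) {
      ranksum_p(small, big[sample.int(length(big), ns)])
    }, numeric(1))
    median(ps)
  })
}

#' Same-species series within a search radius
#'
#' Selects, from a candidate sensitivity table, the series of the focal
#' site's species whose site lies within `radius_km` (great-circle) of the
#' focal site.
#'
#' @param focal One-row tibble with `lat`, `lon` and (unless `species` is
#'   given) `species`.
#' @param candidates Sensitivity table with `lat`, `lon`, `species`.
#' @param radius_km Search radius, default 100 km.
#' @param species Species code; defaults to the focal site's.
#' @return The qualifying subset of `candidates`.
#' @export
neighbors_within_radius <- function(focal, candidates, radius_km = 100,
                                    species = NULL) {
  species <- species %||% focal$species[1]
  cand <- candidates[candidates$species == species, ]
  if (!nrow(cand)) return(cand)
  d <- haversine_km(focal$lat[1], focal$lon[1], cand$lat, cand$lon)
  cand[d <= radius_km, ]
}

#' Local median contrasts of targeted vs representative statistics
#'
#' For every targeted (focal) site and statistic, contrasts the median over
#' the focal site's targeted series against the median over all
#' representative series of the same species within `radius_km`
#' (targeted minus representative), with significance from
#' [bootstrap_wilcoxon()].  Focal sites with fewer than `min_neighbors`
#' qualifying representative series are discarded and listed in the
#' `"discarded"` attribute.
#'
#' @param sens Sensitivity table with a `database` column holding
#'   `"targeted"` and `"representative"`.
#' @param radius_km Neighborhood radius, default 100 km.
#' @param statistics Statistics to contrast.
#' @param min_neighbors Minimum representative neighbors, default 10.
#' @param iterations Bootstrap iterations per test, default 1000.
#' @param alpha Significance level, default 0.01.
#' @param seed Optional integer seed; per-focal-site streams are derived
#'   from it.
#' @return Contrast tibble, one row per retained focal site and statistic;
#'   attribute `discarded` lists dropped sites.
#' @export
site_contrasts <- function(sens, radius_km = 100,
                           statistics = c("sd", "beta_precip", "beta_fallT",
                                          "beta_summerT", "r2"),
                           min_neighbors = 10, iterations = 1000,
                           alpha = 0.01, seed = NULL) {
  stop_if_missing_cols(sens, c("site_id", "database", "lat", "lon",
                               "species", statistics), "`sens`")
  targ <- sens[sens$database == "targeted", ]
  repr <- sens[sens$database == "representative", ]
  focals <- dplyr::distinct(targ, .data$site_id, .data$species,
                            .data$lat, .data$lon)
  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(focals))) {
    f <- focals[i, ]
    tvals <- targ[targ$site_id == f$site_id & targ$species == f$species, ]
    nb <- neighbors_within_radius(f, repr, radius_km)
    if (nrow(nb) < min_neighbors) {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        focal_site_id = f$site_id, species = f$species,
        n_representative = nrow(nb))
      next
    }
    for (st in statistics) {
      p <- bootstrap_wilcoxon(tvals[[st]], nb[[st]], iterations,
                              seed = if (is.null(seed)) NULL else seed + i)
      mt <- median(tvals[[st]])
      mr <- median(nb[[st]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        focal_site_id = f$site_id, species = f$species, statistic = st,
        median_targeted = mt, median_representative = mr,
        contrast = mt - mr, n_targeted = nrow(tvals),
        n_representative = nrow(nb), p_value = p,
        significant = p < alpha
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "discarded") <- dplyr::bind_rows(dropped)
  out
}
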