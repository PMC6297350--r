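# ggplot2 views of the result objects.  These are diagnostic plots, not
# publication figures; they stay deliberately plain.

#' Plot a regional chronology
#'
#' Index line with the per-year series replication shown as a shaded band
#' at the bottom.
#'
#' @param object A `ring_chronology`.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot ring_chronology
#' @export
autoplot.ring_chronology <- function(object, ...) {
  d <- tibble::as_tibble(object)
  scale <- 0.25 * diff(range(d$value)) / max(d$n_t)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_area(ggplot2::aes(y = min(d$value) + .data$n_t * scale),
                       fill = "grey80") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$value)) +
    ggplot2::labs(x = "Year", y = "Ring-width index",
                  subtitle = "Shaded band: series replication (scaled)") +
    ggplot2::theme_minimal()
}

#' Plot projected future growth
#'
#' Boxplots of projected mean ring-width index across GCMs, per period and
#' database.
#'
#' @param object A `ring_projection` from [project_growth()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ring_projection
#' @export
autoplot.ring_projection <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$period, y = .data$mean_rwi,
                               fill = .data$database)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Period", y = "Projected mean ring-width index",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot local median contrasts
#'
#' Contrast (targeted minus representative) per focal site and statistic;
#' filled points are significant at the configured alpha.
#'
#' @param contrasts Output of [site_contrasts()].
#' @return A ggplot.
#' @export
plot_contrasts <- function(contrasts) {
  ggplot2::ggplot(contrasts,
                  ggplot2::aes(x = .data$focal_site_id, y = .data$contrast,
                               colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "Focal targeted site",
                  y = "Median contrast (targeted - representative)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
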