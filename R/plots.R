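#' Plot a median profile with its 95% quantile band
#'
#' @param band Output of [profile_band()].
#' @return A ggplot object.
#' @export
plot_profile_band <- function(band) {
  ggplot2::ggplot(band, ggplot2::aes(x = .data$temperature)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "goldenrod", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$center), linewidth = 0.6) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(C[p]^{ex} ~ "(cal/" * degree * "C·g)"),
                  title = "Median profile and 95% quantile interval") +
    ggplot2::theme_minimal()
}

#' Plot mean follow-up minus baseline difference profiles by phenotype
#'
#' @param diffs Output of [mean_difference_profile()].
#' @return A ggplot object.
#' @export
plot_difference_profiles <- function(diffs) {
  ggplot2::ggplot(diffs,
                  ggplot2::aes(x = .data$temperature, y = .data$mean_diff,
                               colour = .data$phenotype)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = "Mean difference (Tfu − T0)",
                  colour = "Phenotype") +
    ggplot2::theme_minimal()
}

#' Box plots of a metric across phenotype groups
#'
#' @param panels Metric-panel tibble with a grouping column.
#' @param metric Metric column name.
#' @param group Grouping column name (default `"phenotype"`).
#' @return A ggplot object.
#' @export
plot_metric_box <- function(panels, metric, group = "phenotype") {
  ggplot2::ggplot(panels,
                  ggplot2::aes(x = .data[[group]], y = .data[[metric]],
                               fill = .data[[group]])) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Faceted cluster-center plot for a thermogram k-means fit
#'
#' @param object A `tlb_kmeans` object.
#' @param ... Unused.
#' @return A ggplot object: one facet per cluster showing its center curve.
#' @method autoplot tlb_kmeans
#' @export
autoplot.tlb_kmeans <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble(cluster = paste0("Cluster ", j, " (n = ", object$sizes[[j]], ")"),
           temperature = tlb_grid(),
           cp_excess = object$centers[j, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature,
                                   y = .data$cp_excess)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(C[p]^{ex} ~ "(cal/" * degree * "C·g)")) +
    ggplot2::theme_minimal()
}
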