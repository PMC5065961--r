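# ggplot2 views of the result objects.

#' Plot a source-contribution raster
#'
#' Filled-tile map of the footprint with the receptor marked.
#'
#' @param object A `source_raster`.
#' @param trim Drop cells below this fraction of the maximum (declutters
#'   the long tail).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.source_raster <- function(object, trim = 0.001, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$value >= trim * max(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_tile(width = object$res, height = object$res) +
    ggplot2::annotate("point", x = object$receptor$lon,
                      y = object$receptor$lat, shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(trans = "sqrt", name = "contribution") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  title = "Source-contribution footprint")
}

#' Plot a raster-series correlogram
#'
#' Per-bird mean correlation against lag (thin lines) with the grand mean
#' and +/- one standard deviation across birds.
#'
#' @param object A `plume_correlogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plume_correlogram <- function(object, ...) {
  ggplot2::ggplot(object$by_bird,
                  ggplot2::aes(.data$lag, .data$mean_r,
                               group = .data$bird_id)) +
    ggplot2::geom_line(alpha = 0.35, colour = "grey50") +
    ggplot2::geom_line(data = object$summary,
                       ggplot2::aes(.data$lag, .data$grand_mean,
                                    group = NULL), linewidth = 1) +
    ggplot2::geom_line(data = object$summary,
                       ggplot2::aes(.data$lag,
                                    .data$grand_mean + .data$grand_sd,
                                    group = NULL), linetype = 2) +
    ggplot2::geom_line(data = object$summary,
                       ggplot2::aes(.data$lag,
                                    .data$grand_mean - .data$grand_sd,
                                    group = NULL), linetype = 2) +
    ggplot2::labs(x = "lag (h)", y = "mean correlation",
                  title = "Dispersion-field correlogram")
}

#' Boxplot of accumulation scores by treatment group
#'
#' @param scores Tibble from [accumulation_score()] rows.
#' @return A ggplot.
#' @export
plot_accumulation <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(.data$group, .data$score)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "accumulated particles per location",
                  title = "Accumulated-particle score by group")
}

#' Turn angle against plume-arrival angle
#'
#' Scatter of the signed turn against the signed plume-relative arrival
#' angle with the OLS fit, for the reoriented birds.
#'
#' @param turns Tibble of classified turn records.
#' @return A ggplot.
#' @export
plot_turn_relation <- function(turns) {
  df <- dplyr::filter(turns, is.finite(.data$delta),
                      is.finite(.data$plume_relative_angle))
  ggplot2::ggplot(df, ggplot2::aes(.data$plume_relative_angle,
                                   .data$delta)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "plume arrival angle relative to flight (deg)",
                  y = "turn after exposure (deg)",
                  title = "Reorientation vs plume-arrival angle")
}
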