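#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a habitat grid
#'
#' @param object A [habitat_grid()].
#' @param ... Unused.
#' @return A ggplot raster map with one fill per class.
#' @method autoplot habitat_grid
#' @export
autoplot.habitat_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a continuous grid
#'
#' @param object A [continuous_grid()].
#' @param ... Unused.
#' @return A ggplot raster map.
#' @method autoplot continuous_grid
#' @export
autoplot.continuous_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$col, y = -.data$row,
    fill = .data[[object$name]]
  )) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted maxent model
#'
#' @param object A [maxent_fit()] model.
#' @param nonzero_only Show only features with nonzero coefficients.
#' @param ... Unused.
#' @return A ggplot dot plot of coefficients.
#' @method autoplot maxent_model
#' @export
autoplot.maxent_model <- function(object, nonzero_only = TRUE, ...) {
  df <- tidy(object)
  if (nonzero_only) df <- df[df$estimate != 0, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$estimate,
    y = stats::reorder(.data$feature, .data$estimate),
    colour = .data$predictor
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a regularisation selection report
#'
#' @param report The report tibble from [select_beta()].
#' @return A ggplot of AICc against beta, with the winner highlighted.
#' @export
plot_fit_report <- function(report) {
  best <- report[which.min(report$aicc), ]
  ggplot2::ggplot(report, ggplot2::aes(x = .data$beta, y = .data$aicc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = best, colour = "red", size = 3) +
    ggplot2::labs(x = expression(beta), y = "AICc") +
    ggplot2::theme_minimal()
}

#' Box plots of suitable-area proportions per scenario
#'
#' Mirrors the standard presentation of scenario ensembles: one box per
#' scenario (nulls beside their scenario), facetted by threshold, with a
#' dotted line at the baseline landscape's suitable proportion.
#'
#' @param records Tibble with `scenario`, `run`, `threshold_name`,
#'   `proportion_suitable` (see [project_ensembles()]).
#' @param baseline Optional named vector of baseline proportions per
#'   threshold name (drawn as dotted lines).
#' @return A ggplot.
#' @export
plot_suitable_area <- function(records, baseline = NULL) {
  p <- ggplot2::ggplot(records, ggplot2::aes(
    x = .data$scenario,
    y = .data$proportion_suitable
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~threshold_name, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "proportion of study area suitable") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(baseline)) {
    bl <- tibble::tibble(
      threshold_name = names(baseline),
      proportion_suitable = unname(baseline)
    )
    p <- p + ggplot2::geom_hline(
      data = bl,
      ggplot2::aes(yintercept = .data$proportion_suitable),
      linetype = "dotted"
    )
  }
  p
}

#' Box plots of suitable-area proportions across extent levels
#'
#' @param records Tibble with a `level` column in addition to the
#'   [plot_suitable_area()] columns.
#' @param baseline Optional baseline proportion (dotted line).
#' @return A ggplot of proportion against conversion extent.
#' @export
plot_extent_sweep <- function(records, baseline = NULL) {
  p <- ggplot2::ggplot(records, ggplot2::aes(
    x = factor(.data$level),
    y = .data$proportion_suitable
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "conversion extent (%)", y = "proportion of study area suitable") +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline, linetype = "dotted")
  }
  p
}
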