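#' Plot a change grid
#'
#' Map of per-cell net harvested-area change with the contraction/expansion
#' classification: contracting cells in red, expanding in blue, unchanged in
#' grey; cells below the display minimum are blank.
#'
#' @param object A `change_grid` from [classify_change()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot change_grid
#' @export
autoplot.change_grid <- function(object, ...) {
  d <- dplyr::filter(object, .data$displayed)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$change_class)) +
    ggplot2::scale_fill_manual(
      values = c(contracting = "#c0392b", none = "grey85", expanding = "#2471a3"),
      drop = FALSE, name = "Area change"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "column", y = "row (north at top)",
      title = "Net cropland change between epochs"
    ) +
    ggplot2::theme_minimal()
}

#' Plot site yields by side
#'
#' Mean annual yield potential per site, split by contracting/expanding flag,
#' point size proportional to the absolute net area balance (the upscaling
#' weight).
#'
#' @param sites Site tibble (e.g. `run_pipeline(...)$sites`).
#' @return A ggplot.
#' @export
plot_site_yields <- function(sites) {
  assert_columns(sites, c("mean_annual_yield", "net_balance", "flag"), "sites")
  d <- dplyr::filter(sites, as.character(.data$flag) != "none")
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = as.character(.data$flag), y = .data$mean_annual_yield,
      size = abs(.data$net_balance)
    )
  ) +
    ggplot2::geom_point(alpha = 0.7, colour = "#1a5276") +
    ggplot2::scale_size_area(name = "|net balance| (ha)") +
    ggplot2::labs(
      x = NULL, y = "annual yield potential (t/ha/yr)",
      title = "Site yield potential by change side"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a yield-ratio report
#'
#' Side-by-side national weighted annual yield potential with the yield
#' ratio annotated.
#'
#' @param object A `yield_ratio_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot yield_ratio_report
#' @export
autoplot.yield_ratio_report <- function(object, ...) {
  s <- object$sides
  lab <- if (object$ratio_defined) {
    sprintf("national yield ratio = %.1f", object$ratio_1dp)
  } else {
    "ratio undefined"
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$side, y = .data$yield_t_ha, fill = .data$side)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(contracting = "#c0392b", expanding = "#2471a3")) +
    ggplot2::labs(
      x = NULL, y = "weighted annual yield potential (t/ha)",
      title = "Converted vs new cropland", subtitle = lab
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
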