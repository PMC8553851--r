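#' Map a per-cell value on the analysis grid
#'
#' A ggplot tile map of any per-cell quantity (richness, a beta-diversity
#' score, importance, protection fraction) in geographic coordinates.
#'
#' @param data Tibble with `row`, `col` columns (and a `grid` attribute or an
#'   explicit `grid`).
#' @param value Column to map; tidy-eval.
#' @param grid Optional [grid_spec()]; default: the tibble's `grid` attribute.
#' @return A ggplot object.
#' @export
plot_cell_map <- function(data, value, grid = NULL) {
  grid <- grid %||% grid_attr(data)
  res <- grid$resolution
  df <- dplyr::mutate(data,
                      lon = grid$lon_min + (.data$col + 0.5) * res,
                      lat = grid$lat_max - (.data$row + 0.5) * res)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = {{ value }})) +
    ggplot2::geom_tile(width = res, height = res) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' @rdname fit_protection_logistic
#' @param object A `protection_fit`.
#' @method autoplot protection_fit
#' @export
autoplot.protection_fit <- function(object, ...) {
  span <- object$range_span
  curve <- tibble::tibble(
    range_cells = seq(span[1], span[2], length.out = 200))
  curve$p <- plogis(object$intercept + object$slope * curve$range_cells)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$range_cells, .data$protected)) +
    ggplot2::geom_jitter(height = 0.02, width = 0, alpha = 0.5) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p),
                       linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "Range size (cells)",
                  y = "P(inside a conservation unit)") +
    ggplot2::theme_minimal()
}

#' @rdname pca_reduce
#' @param object An `env_pca`.
#' @method autoplot env_pca
#' @export
autoplot.env_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$cumulative_variance)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$explained_variance),
                      fill = "grey70") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$target_cumvar, linetype = 2) +
    ggplot2::labs(x = "Principal component",
                  y = "Variance fraction (bars: per axis, line: cumulative)") +
    ggplot2::theme_minimal()
}
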