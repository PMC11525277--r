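#' Map a gridded series
#'
#' Draws the time-mean of a `grid_series` as a raster map (row 1 at the
#' top), or monthly facets for the requested timestamps.
#'
#' @param object A `grid_series`.
#' @param timestamps Optional tibble/data frame of (year, month) rows to
#'   facet; default is the time-mean map.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grid_series
#' @export
autoplot.grid_series <- function(object, timestamps = NULL, ...) {
  if (is.null(timestamps)) {
    df <- object |>
      dplyr::group_by(.data$row, .data$col) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::labs(fill = grid_variable(object),
                    title = paste("Time mean of", grid_variable(object)))
  } else {
    df <- dplyr::semi_join(tibble::as_tibble(object),
                           tibble::as_tibble(timestamps), by = c("year", "month"))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~ year + month) +
      ggplot2::labs(fill = grid_variable(object))
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::theme_minimal()
}

#' Regional index envelope over time
#'
#' The spatial minimum, mean and maximum of the index at each month across
#' all pixels -- the regional summary view of a combined index series.
#'
#' @param index A `grid_series`.
#' @return A ggplot object.
#' @export
plot_index_envelope <- function(index) {
  df <- index |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(min = min(.data$value, na.rm = TRUE),
                     mean = mean(.data$value, na.rm = TRUE),
                     max = max(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(date = .data$year + (.data$month - 0.5) / 12)
  ggplot2::ggplot(df, ggplot2::aes(.data$date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "steelblue") +
    ggplot2::labs(x = "year", y = grid_variable(index),
                  title = "Regional min / mean / max") +
    ggplot2::theme_minimal()
}

#' Map entropy weights per indicator
#'
#' @param object An [entropy_weights()] object.
#' @param ... Unused.
#' @return A ggplot object faceted by indicator.
#' @method autoplot entropy_weights
#' @export
autoplot.entropy_weights <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$col, .data$row, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~ indicator) +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(title = "Entropy weights", fill = "W") +
    ggplot2::theme_minimal()
}

#' Map hotspot layers
#'
#' Facets the hotspot summary layers (mean annual severity/duration, drought
#' month counts, propensities) as raster maps; lighter cells mark higher
#' drought risk for count layers.
#'
#' @param object A [hotspot_stack()].
#' @param layers Character vector of layer columns to draw (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hotspot_stack
#' @export
autoplot.hotspot_stack <- function(object, layers = NULL, ...) {
  value_cols <- setdiff(names(object), c("row", "col", "n_events"))
  layers <- layers %||% value_cols
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(layers), names_to = "layer") |>
    dplyr::group_by(.data$layer) |>
    dplyr::mutate(value = (.data$value - min(.data$value, na.rm = TRUE)) /
                    max(1e-12, diff(range(.data$value, na.rm = TRUE)))) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~ layer) +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(title = "Drought hotspot layers", fill = "scaled") +
    ggplot2::theme_minimal()
}
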