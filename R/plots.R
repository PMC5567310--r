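#' Map a per-cell quantity on the hexagonal grid
#'
#' @param grid A [hex_grid()].
#' @param values Tibble with `cell_id` and the column named in `fill`.
#' @param fill Name of the value column to map.
#' @return A ggplot object.
#' @export
plot_cell_map <- function(grid, values, fill = "we") {
  df <- dplyr::bind_rows(lapply(seq_len(nrow(grid$cells)), function(i) {
    g <- grid$cells$geometry[[i]]
    tibble::tibble(cell_id = grid$cells$cell_id[i], x = g[, 1], y = g[, 2])
  }))
  df <- dplyr::left_join(df, values, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$cell_id,
                                   fill = .data[[fill]])) +
    ggplot2::geom_polygon(color = "grey30", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = fill) +
    ggplot2::theme_minimal()
}

#' Plot protection accumulation curves
#'
#' @param accumulation Result of [accumulation_curves()].
#' @return A ggplot object.
#' @export
plot_accumulation <- function(accumulation) {
  ggplot2::ggplot(accumulation$series,
                  ggplot2::aes(.data$year, .data$pct_of_final,
                               color = .data$dimension)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "designation year", y = "% of final protection") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gap_report <- function(object, ...) {
  ggplot2::ggplot(object$overall,
                  ggplot2::aes(.data$dimension, .data$pct_outside)) +
    ggplot2::geom_col(fill = "#31688e") +
    ggplot2::labs(x = NULL, y = "% outside protected areas") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sdm_summary <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$group, .data$median,
                               ymin = .data$q25, ymax = .data$q75,
                               color = .data$group)) +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(x = NULL, y = "% of predicted range inside PAs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.sdm_fit <- function(object, ...) {
  tibble::tibble(suitability = object$suitability) |>
    ggplot2::ggplot(ggplot2::aes(.data$suitability)) +
    ggplot2::geom_histogram(bins = 40, fill = "#35b779") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "suitability", y = "cells") +
    ggplot2::theme_minimal()
}
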