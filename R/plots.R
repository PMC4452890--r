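#' Plot co-occurrence query results
#'
#' Scatter of observed against expected co-occurrence on a log scale,
#' colored by classification and faceted by mode. Pairs far below the
#' diagonal co-occur more rarely than chance predicts — the functional
#' dissimilarity signal.
#'
#' @param object A `cooc_pairs` tibble from [query_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cooc_pairs
#' @export
autoplot.cooc_pairs <- function(object, ...) {
  df <- filter(as_tibble(object), .data$category != "NA")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$k,
                                   colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::facet_wrap(ggplot2::vars(.data$mode)) +
    ggplot2::labs(x = "expected co-occurrence (K n / N)",
                  y = "observed co-occurrence (k)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dissimilarity summary
#'
#' Stacked bar of the Dissimilar / NotDissimilar / NA fractions per mode.
#'
#' @param object A `cooc_summary` from [summarize_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cooc_summary
#' @export
autoplot.cooc_summary <- function(object, ...) {
  df <- as_tibble(object) |>
    select("mode", "dissimilar", "not_dissimilar", "na") |>
    tidyr::pivot_longer(-"mode", names_to = "category", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$fraction,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of term pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
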