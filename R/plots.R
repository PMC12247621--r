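#' Heatmap of a quantity over the (gamma, omega) grid
#'
#' @param df a tibble with `gamma`, `omega` and the mapped value column.
#' @param value column to map to fill (tidy-eval).
#' @return a ggplot.
#' @export
plot_parameter_map <- function(df, value) {
  value <- rlang::enquo(value)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$gamma),
                                   y = factor(.data$omega),
                                   fill = !!value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(gamma), y = expression(omega)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flex_pca <- function(object, component = "PC1", ...) {
  plot_parameter_map(object$scores, .data[[component]]) +
    ggplot2::labs(fill = paste(component, "score"))
}

#' @export
autoplot.flexibility_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$layer, y = .data$flexibility)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "layerwise flexibility") +
    ggplot2::theme_minimal()
}

#' Layer-pair switching heatmap
#'
#' @param x a `layer_switch` result.
#' @return a ggplot.
#' @export
plot_switch_matrix <- function(x) {
  stopifnot(inherits(x, "layer_switch"))
  df <- tidy(x)
  df2 <- df
  names(df2)[1:2] <- c("layer_b", "layer_a")
  both <- dplyr::bind_rows(df, df2)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$layer_a, y = .data$layer_b,
                                     fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "switch\nproportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Flexibility by system
#'
#' @param flex a `flexibility_profile`.
#' @param parcellation parcellation tibble.
#' @param level grouping column.
#' @return a ggplot ordered by median flexibility.
#' @export
plot_system_flexibility <- function(flex, parcellation, level = "system") {
  df <- tibble::tibble(
    node = seq_along(flex$overall) - 1L,
    flexibility = flex$overall)
  df <- dplyr::inner_join(
    df, parcellation[, c("node_id", level)],
    by = c(node = "node_id"))
  df$group <- stats::reorder(df[[level]], df$flexibility, FUN = median)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$flexibility)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "flexibility") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
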