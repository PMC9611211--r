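#' Plot removal dynamics
#'
#' Mean removal over time per system, faceted by pollutant.
#'
#' @param x A removal table.
#' @return A ggplot.
#' @export
plot_removal_curves <- function(x) {
  x <- validate_removal_table(x)
  x |>
    dplyr::group_by(.data$system, .data$pollutant, .data$day) |>
    dplyr::summarise(removal = mean(.data$removal), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(.data$day, .data$removal,
                                 colour = .data$system)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pollutant)) +
    ggplot2::labs(x = "Day", y = "Removal fraction", colour = "System") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cw_score_result <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$day, .data$E, colour = .data$system)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Day", y = "Composite score E", colour = "System") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cw_factor_model <- function(object, ...) {
  if (is.null(object$loadings_rotated)) object <- rotate_factors(object)
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$factor, .data$indicator,
                                 fill = .data$loading_rotated)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$loading_rotated))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Loading") +
    ggplot2::theme_minimal()
}

#' Plot a taxon-by-variable correlation heatmap
#'
#' Tiles coloured by rho; significant cells (raw p < 0.05) are starred.
#'
#' @param cor_tbl Output of [correlation_table()].
#' @return A ggplot.
#' @export
plot_correlation_heatmap <- function(cor_tbl) {
  cw_assert_cols(cor_tbl, c("taxon", "variable", "rho", "significant"),
                 "correlation table")
  ggplot2::ggplot(cor_tbl, ggplot2::aes(.data$variable, .data$taxon,
                                        fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", ""))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal()
}

#' Plot alpha-diversity indices by sample
#'
#' @param x Output of [alpha_table()].
#' @return A ggplot.
#' @export
plot_alpha <- function(x) {
  cw_assert_cols(x, c("sample", "chao1", "shannon", "simpson"),
                 "alpha table")
  long <- tidyr::pivot_longer(
    x, cols = dplyr::any_of(c("otus", "chao1", "shannon", "simpson",
                              "coverage")),
    names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
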