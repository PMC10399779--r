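#' Decile histogram of social maturity scores
#'
#' @param maturity Numeric vector of maturity scores in \[0, 1\].
#' @return A ggplot showing the characteristic U shape of a polarized colony.
#' @export
plot_maturity_distribution <- function(maturity) {
  diag <- maturity_distribution_diagnostic(maturity)
  ggplot2::ggplot(diag$histogram,
                  ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = 0.095, fill = "grey30") +
    ggplot2::labs(x = "social maturity", y = "workers",
                  subtitle = sprintf("outer/middle decile mass ratio: %.2f",
                                     diag$outer_middle_ratio)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.correlation_network <- function(object, ...) {
  df <- as_tibble(object$average, rownames = "variable_1") %>%
    tidyr::pivot_longer(-"variable_1", names_to = "variable_2",
                        values_to = "r_squared")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable_1, y = .data$variable_2,
                                   fill = .data$r_squared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r_squared)),
                       color = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(R^2),
                  subtitle = sprintf("hub: %s", object$hub)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prediction_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$variable, y = .data$r_squared)) +
    ggplot2::geom_boxplot(width = 0.4) +
    ggplot2::labs(x = NULL, y = expression(R^2~"(predicted vs observed)")) +
    ggplot2::theme_minimal()
}

#' Box plots of prediction accuracy across variables
#'
#' @param results List of `"prediction_result"` objects.
#' @return A ggplot of per-iteration R-squared distributions, ordered by mean.
#' @export
plot_prediction_ranking <- function(results) {
  df <- dplyr::bind_rows(purrr::map(results, tidy))
  ord <- df %>%
    group_by(.data$variable) %>%
    summarise(m = mean(.data$r_squared), .groups = "drop") %>%
    arrange(dplyr::desc(.data$m))
  df$variable <- factor(df$variable, levels = ord$variable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$r_squared)) +
    ggplot2::geom_boxplot(width = 0.4) +
    ggplot2::labs(x = NULL, y = expression(R^2~"(predicted vs observed)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
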