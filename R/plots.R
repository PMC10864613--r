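#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of disproportionality signals
#'
#' Reporting odds ratios with 95% intervals on a log scale, strongest terms
#' first; consensus signals are highlighted.
#'
#' @param object A `dispro_result`.
#' @param top_n Terms shown (by case count).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dispro_result
#' @export
autoplot.dispro_result <- function(object, top_n = 20, ...) {
  df <- rank_signals(object, "case_number") %>%
    dplyr::filter(!is.na(.data$ror)) %>%
    utils::head(top_n) %>%
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$term,
                                   colour = .data$consensus)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ror_low, xmax = .data$ror_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey40"),
                                 name = "consensus") +
    ggplot2::labs(x = "reporting odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Onset-interval histogram with the fitted Weibull density
#'
#' @param object A `weibull_fit`.
#' @param binwidth Histogram bin width in days.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weibull_fit
#' @export
autoplot.weibull_fit <- function(object, binwidth = 15, ...) {
  df <- tibble::tibble(days = pmax(object$days, 0.5))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$days)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey75", colour = "white") +
    ggplot2::labs(x = "time to onset (days)", y = "density") +
    ggplot2::theme_minimal()
  if (isTRUE(object$converged)) {
    p <- p + ggplot2::stat_function(
      fun = stats::dweibull,
      args = list(shape = object$shape, scale = object$scale),
      colour = "#2c3e50", linewidth = 0.8
    )
  }
  p
}

#' Bar chart of onset periods
#'
#' @param periods Tibble from [tto_periods()].
#' @return A ggplot object.
#' @export
plot_tto_periods <- function(periods) {
  df <- dplyr::mutate(periods, period = factor(.data$period, levels = .data$period))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$n)) +
    ggplot2::geom_col(fill = "#2980b9") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "time to onset (days)", y = "reports") +
    ggplot2::theme_minimal()
}
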