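# ggplot2 methods for the package's result types.

#' Plot a substitution spectrum
#'
#' Bars of calls per 10 Mb for the twelve substitution classes, with
#' Poisson error bars (sqrt(count), scaled like the rates).
#'
#' @param object A `spectrum_result` from [substitution_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum_result
#' @export
autoplot.spectrum_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$class, y = .data$rate_per_10mb)) +
    ggplot2::geom_col(fill = "#2c5d87") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate_per_10mb - .data$poisson_se,
                   ymax = .data$rate_per_10mb + .data$poisson_se),
      width = 0.3
    ) +
    ggplot2::labs(x = "Substitution class", y = "Calls per 10 Mb") +
    ggplot2::theme_minimal()
}

#' Plot a spectrum contrast
#'
#' Side-by-side per-class rates of the two contrasted call sets with
#' Poisson error bars; deamination artifacts appear as an excess of the
#' C>T and G>A bars in call set b.
#'
#' @param object A `spectrum_contrast` from [spectrum_contrast()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum_contrast
#' @export
autoplot.spectrum_contrast <- function(object, ...) {
  scale <- attr(object, "genome_size") / 1e7
  long <- as_tibble(object) |>
    select("class", "rate_a", "rate_b") |>
    tidyr::pivot_longer(c("rate_a", "rate_b"),
                        names_to = "callset", values_to = "rate",
                        names_prefix = "rate_")
  long$se <- sqrt(long$rate * scale) / scale
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$class, y = .data$rate,
                               fill = .data$callset)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate - .data$se,
                   ymax = .data$rate + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3
    ) +
    ggplot2::scale_fill_manual(values = c(a = "#2c5d87", b = "#d95f02")) +
    ggplot2::labs(x = "Substitution class", y = "Calls per 10 Mb",
                  fill = "Call set") +
    ggplot2::theme_minimal()
}

#' Plot a prioritization report
#'
#' Tier-by-tier surviving variant counts per case (and shared), on a log10
#' scale with zero counts shown at the axis floor.
#'
#' @param object A `prioritization_report` from [prioritize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prioritization_report
#' @export
autoplot.prioritization_report <- function(object, ...) {
  counts <- object$counts
  counts$n_plot <- pmax(counts$n, 0.5)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$tier, y = .data$n_plot,
                               group = .data$sample,
                               colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.8,
                       show.legend = FALSE, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Surviving variants", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20,
                                                       hjust = 1))
}
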