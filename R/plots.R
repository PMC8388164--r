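# ggplot2 methods for the result objects.

#' Plot a cost-effectiveness acceptability curve
#'
#' Probability that each strategy is the most cost-effective option (highest
#' net monetary benefit) across the willingness-to-pay grid.
#'
#' @param object A `crc_ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_ceac
#' @export
autoplot.crc_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (£ per QALY)",
                  y = "Probability most cost-effective",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot incremental outcomes by stratum
#'
#' Bar chart of incremental cost, QALYs, net monetary benefit and clinical
#' outcomes per 100,000 versus the comparator, for men, women and the whole
#' population.
#'
#' @param object A `crc_comparison` from [compare_strategies()].
#' @param measures Columns of the comparison to facet over.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_comparison
#' @export
autoplot.crc_comparison <- function(object,
                                    measures = c("d_cost", "d_qaly", "nmb",
                                                 "d_crc_cases_100k",
                                                 "d_crc_deaths_100k"),
                                    ...) {
  df <- tidy(object)
  df <- df[df$strategy != attr(object, "comparator"), ]
  long <- tidyr::pivot_longer(df[c("strategy", "stratum", measures)],
                              dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy, y = .data$value,
                                     fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Increment vs comparator", fill = "Stratum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the scenario grid
#'
#' Incremental net monetary benefit of each grid member versus the
#' fixed-age-60 comparator, by mean start age and sex gap.
#'
#' @param object A `crc_grid` from [scenario_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_grid
#' @export
autoplot.crc_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$gap), y = .data$d_nmb,
                                       fill = factor(.data$mean_start))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~threshold) +
    ggplot2::labs(x = "Sex gap in start age (years)",
                  y = "Incremental NMB vs comparator (£ per person)",
                  fill = "Mean start age") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
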