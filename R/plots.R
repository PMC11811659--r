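#' Density plots of the indicators per expertise group
#'
#' Mirrors the standard presentation of known-groups results: one density
#' panel per indicator, coloured by group, with dashed lines at the group
#' means.
#'
#' @param indicators Indicator tibble (see [run_battery()]).
#' @param which Indicator columns to plot.
#' @return A ggplot object.
#' @export
plot_indicator_densities <- function(indicators,
                                     which = c("accuracy", "std_speed",
                                               "efficiency")) {
  long <- indicators |>
    dplyr::select("participant_id", "group", dplyr::all_of(which)) |>
    tidyr::pivot_longer(dplyr::all_of(which),
                        names_to = "indicator", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  means <- long |>
    dplyr::group_by(.data$indicator, .data$group) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(
      data = means,
      ggplot2::aes(xintercept = .data$value, colour = .data$group),
      linetype = "dashed", show.legend = FALSE
    ) +
    ggplot2::facet_wrap(~indicator, scales = "free") +
    ggplot2::labs(x = NULL, y = "density", fill = "group") +
    ggplot2::theme_minimal()
}

#' Effect-size overview of a battery report
#'
#' Dot plot of Cohen's d for the univariate known-groups tests.
#'
#' @param object An `mci_battery` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mci_battery <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$cohen_d, y = stats::reorder(.data$indicator, .data$cohen_d))
  ) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Cohen's d (MFR vs non-MFR)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
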