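#' Plot a batch-culture time series
#'
#' Growth-profile plot of a culture time series: biomass, glucose and
#' ethanol (plus any non-zero by-products) against time, the standard
#' way a batch fermentation is inspected for the
#' make-accumulate-consume shape.
#'
#' @param ts A `culture_ts` tibble.
#' @param log_biomass Plot biomass on a log axis panel? (default
#'   `FALSE`: single linear panel).
#' @return A ggplot object.
#' @export
plot_culture <- function(ts, log_biomass = FALSE) {
  long <- tibble::as_tibble(ts) %>%
    dplyr::select(dplyr::all_of(c("time_h", "dw_gL", "glucose_gL",
                                  PRODUCT_COLUMNS))) %>%
    tidyr::pivot_longer(-"time_h", names_to = "signal",
                        values_to = "g_per_L") %>%
    dplyr::group_by(.data$signal) %>%
    dplyr::filter(any(.data$g_per_L > 0)) %>%
    dplyr::ungroup()
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$g_per_L,
                                          colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (g/L)",
                  colour = NULL,
                  title = attr(ts, "strain") %||% NULL) +
    ggplot2::theme_minimal()
  if (log_biomass) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.culture_ts <- function(object, ...) plot_culture(object, ...)

#' Plot group means with confidence intervals
#'
#' Bar chart of per-group parameter means with their confidence
#' intervals, one facet per parameter - the group-comparison view of
#' the four physiological parameters.
#'
#' @param group_summary Tibble from [group_mean_ci()] (possibly
#'   row-bound over several parameters).
#' @return A ggplot object.
#' @export
plot_group_means <- function(group_summary) {
  ggplot2::ggplot(group_summary,
                  ggplot2::aes(.data$group, .data$mean,
                               fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.25) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "phylogenetic group", y = "group mean (95% CI)") +
    ggplot2::theme_minimal()
}
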