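## ggplot2 views of the main result types.

#' Concentration-time profiles
#'
#' Pre-filter (or any single site) profiles on a log concentration scale,
#' one line per experiment, faceted by filter.
#'
#' @param data Tidy sample table.
#' @param analyte,site Series to plot.
#' @param log_y Log-scale the concentration axis? Default TRUE.
#' @return A ggplot object.
#' @export
plot_concentration_time <- function(data, analyte = "apixaban",
                                    site = "pre_filter", log_y = TRUE) {
  check_samples(data)
  d <- dplyr::filter(data, .data$analyte == .env$analyte,
                     .data$site == .env$site)
  if (!nrow(d)) abort("No samples match the requested analyte/site.")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$conc_ng_mL,
                                       group = .data$experiment_id,
                                       colour = .data$mode)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$filter)) +
    ggplot2::labs(x = "Time (min)", y = "Concentration (ng/mL)",
                  colour = "Mode") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.crrt_adsorption <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$percent,
                                       colour = .data$filter,
                                       group = .data$experiment_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Time (min)", y = "Adsorbed (% of dose)",
                  colour = "Filter") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.crrt_dose_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("flow_rate", "tdd_hf1400", "tdd_m150")],
    cols = -"flow_rate", names_to = "filter", names_prefix = "tdd_",
    values_to = "tdd")
  long$filter <- toupper(long$filter)
  ggplot2::ggplot(long, ggplot2::aes(.data$flow_rate, .data$tdd,
                                     colour = .data$filter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "CRRT flow rate (L/h)",
                  y = "Exact total daily dose (mg)", colour = "Filter") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.crrt_stepfit <- function(object, ...) {
  d <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Effect on CL_TM (L/h)", y = NULL) +
    ggplot2::theme_minimal()
}
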