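#' Plot a response-model sweep
#'
#' Line panels of the main abundance-dependent metrics: consumed numbers by
#' age group, consumed mass, survival, pup difference, female recruitment
#' and the juvenile fraction.
#'
#' @param object an `lhx_sweep` from [response_sweep()].
#' @param metrics columns to facet.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lhx_sweep <- function(object,
                               metrics = c("total_consumed",
                                           "consumed_juveniles",
                                           "mass_consumed_t",
                                           "overall_survival",
                                           "pup_difference",
                                           "female_recruitment",
                                           "j_over_t"),
                               ...) {
  long <- tidyr::pivot_longer(as_tibble(object), all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$abundance_frac,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "abundance (fraction of peak)",
      y = NULL,
      title = sprintf("%s numerical response", attr(object, "kind") %||% "")
    )
}

#' Plot a mortality-event temperature profile
#'
#' @param event an `lhx_event_profile`.
#' @return A ggplot object showing the recorded series and the ambient
#'   level; death is at time 0.
#' @export
plot_event_profile <- function(event) {
  ggplot2::ggplot(event$temp_series,
                  ggplot2::aes(x = .data$time_h, y = .data$temp_c)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = event$ambient_c, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "hours from death", y = "tag temperature (°C)",
                  title = event$event_id %||% event$cause %||% "mortality event")
}
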