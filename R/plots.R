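#' Plot an incubation time series
#'
#' DIN concentrations over time with the 15N enrichment of the NOx pool on
#' a free second panel.
#'
#' @param series An [incubation_series()].
#' @return A ggplot object.
#' @export
plot_incubation <- function(series) {
  stopifnot(inherits(series, "incubation_series"))
  conc <- series$samples |>
    tidyr::pivot_longer(c("nh4", "no2", "no3"),
                        names_to = "species", values_to = "value") |>
    mutate(panel = "concentration (uM)")
  iso <- series$isotope_samples |>
    select("time_h", value = "ape_nox") |>
    mutate(species = "ape_nox", panel = "15N excess (at%)")
  ggplot2::ggplot(bind_rows(conc, iso),
                  ggplot2::aes(x = .data$time_h, y = .data$value,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = sprintf("container %s", series$container_id)) +
    ggplot2::theme_minimal()
}

#' Plot per-treatment rate summaries
#'
#' Mean and standard error of each rate kind by treatment and day, the
#' tabular counterpart of a nitrification-activity figure.
#'
#' @param rates Tidy rates tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_rates <- function(rates) {
  check_cols(rates, c("treatment", "day", "kind", "value"), "rates")
  summary <- rates |>
    group_by(.data$treatment, .data$day, .data$kind) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              se = sd(.data$value, na.rm = TRUE) /
                sqrt(sum(is.finite(.data$value))),
              .groups = "drop")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$day), y = .data$mean,
                               fill = .data$treatment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "day",
                  y = expression(paste(mu, "mol N ", g^-1, " ", d^-1))) +
    ggplot2::theme_minimal()
}
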