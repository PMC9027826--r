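#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs theme_minimal scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Firing rate of each population over time, one facet per population.
#'
#' @param object A `cctc_trajectory`.
#' @param populations Which populations to show; default all.
#' @param from Drop samples before this time (s); default 0.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cctc_trajectory <- function(object, populations = cctc_populations(),
                                     from = 0, ...) {
  d <- object |>
    dplyr::filter(.data$time >= from) |>
    tidyr::pivot_longer(dplyr::all_of(populations),
                        names_to = "population", values_to = "rate") |>
    dplyr::mutate(population = factor(.data$population,
                                      levels = cctc_populations()))
  ggplot(d, aes(x = .data$time, y = .data$rate)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~population, scales = "free_y") +
    labs(x = "time (s)", y = "firing rate (spikes/s)") +
    theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object A `power_spectrum`.
#' @param fmax Upper frequency limit (Hz); default 100.
#' @param log_power Log-scale the power axis; default TRUE.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_spectrum <- function(object, fmax = 100, log_power = TRUE, ...) {
  d <- dplyr::filter(object, .data$frequency <= fmax, .data$frequency > 0)
  p <- ggplot(d, aes(x = .data$frequency, y = .data$power)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "power spectral density") +
    theme_minimal()
  if (log_power) p <- p + scale_y_log10()
  p
}

#' Plot a stimulation waveform
#'
#' @param object A `stim_waveform`.
#' @param max_points Subsample to at most this many points for display;
#'   default 20000.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stim_waveform <- function(object, max_points = 20000, ...) {
  d <- object
  if (nrow(d) > max_points) {
    d <- d[seq(1, nrow(d), length.out = max_points), ]
  }
  ggplot(d, aes(x = .data$time, y = .data$current_mA)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "current (mA)",
         title = paste("stimulation:", attr(object, "kind"))) +
    theme_minimal()
}

#' Plot a closed-loop run
#'
#' Commanded current and the amplitude envelope over time.
#'
#' @param object A `closed_loop_log` from [run_closed_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.closed_loop_log <- function(object, ...) {
  ggplot(object$commands, aes(x = .data$time, y = .data$current_mA)) +
    geom_line(linewidth = 0.2, colour = "grey50") +
    geom_line(aes(y = .data$amplitude), colour = "red") +
    geom_line(aes(y = -.data$amplitude), colour = "red") +
    labs(x = "time (s)", y = "current (mA)",
         title = "closed-loop stimulation command and envelope") +
    theme_minimal()
}

#' Plot region-wise post-pre changes
#'
#' Per-channel change statistics grouped by region.
#'
#' @param object A `region_change` from [post_pre_change()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_change <- function(object, ...) {
  ggplot(object$channels, aes(x = .data$region, y = .data$change)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    geom_point() +
    labs(x = NULL, y = sprintf("post - pre %s change (M)",
                               toupper(object$chromophore))) +
    theme_minimal()
}
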