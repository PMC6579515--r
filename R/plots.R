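#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a time-frequency map
#'
#' Raster of power (log10) or coherence over time and frequency.
#'
#' @param object A [tf_map()].
#' @param fmax Upper frequency limit (Hz), default 100.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tf_map <- function(object, fmax = 100, ...) {
  df <- as_tibble(object)
  df <- df[df$freq_hz <= fmax, ]
  if (object$kind == "power") df$value <- log10(df$value)
  lab <- c(power = "log10 power", coherence = "coherence",
           imaginary_coherency = "imaginary coherency")[object$kind]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab, na.value = "grey90") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a distance profile
#'
#' Value against distance from reward (0 = reward), with occupancy shown as
#' point size.
#'
#' @param object A [distance_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.distance_profile <- function(object, ...) {
  df <- object[is.finite(object$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_center_cm, .data$value)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$occupancy_s), alpha = 0.6) +
    ggplot2::scale_size_continuous(name = "occupancy (s)", range = c(0.2, 2)) +
    ggplot2::labs(x = "distance from reward (cm)", y = "value") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap null with the observed correlation
#'
#' Histogram of the shuffled correlations with the empirical confidence
#' limits and the observed Spearman rho.
#'
#' @param object A `speed_cor_boot` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.speed_cor_boot <- function(object, ...) {
  df <- tibble::tibble(rho = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(.data$rho)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(object$lower, object$upper),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$rho_observed, color = "red") +
    ggplot2::labs(x = "Spearman rho (shuffled)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot coherence spectra by region
#'
#' @param coherence Tibble as in the `coherence` element of a
#'   [run_homecage()] result (columns `region`, `freq_hz`, `coherence`).
#' @param fmax Upper frequency (Hz), default 100.
#' @return A ggplot object.
#' @export
plot_coherence_spectra <- function(coherence, fmax = 100) {
  df <- coherence[coherence$freq_hz <= fmax & coherence$freq_hz >= 1, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$coherence,
                                   color = .data$region)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "coherence") +
    ggplot2::theme_minimal()
}
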