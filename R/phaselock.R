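# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous theta phase of an LFP
#'
#' Zero-phase band-pass (4th-order Butterworth, forward-backward) in the
#' theta band followed by analytic-signal (Hilbert) phase. Phase convention:
#' 0 radians at the oscillation peak, ±pi at the trough, increasing with
#' time. Samples outside `restrict` are set to `NA`.
#'
#' @param lfp A [signal_trace()]; its rate must be at least 4x the band's
#'   upper edge.
#' @param band Length-2 Hz band, default `c(6, 12)`.
#' @param restrict Optional [interval_set()] of times to keep.
#' @return A [signal_trace()] of phase (radians, in `(-pi, pi]`).
#' @export
instantaneous_theta_phase <- function(lfp, band = c(6, 12), restrict = NULL) {
  stopifnot(inherits(lfp, "signal_trace"))
  if (band[1] >= band[2]) stop("band must satisfy f_lo < f_hi", call. = FALSE)
  if (band[2] > lfp$sample_rate / 2) stop("band above Nyquist", call. = FALSE)
  if (lfp$sample_rate < 4 * band[2]) {
    stop("sample rate must be at least 4x the band's upper edge", call. = FALSE)
  }
  filt <- signal::butter(4, band / (lfp$sample_rate / 2), type = "pass")
  xf <- filtfilt_padded(filt, lfp$values)
  ph <- Arg(analytic_signal(xf))
  if (!is.null(restrict)) {
    ph[!interval_contains(restrict, trace_times(lfp))] <- NA_real_
  }
  new_signal_trace(ph, lfp$sample_rate, lfp$t0, label = paste0(lfp$label, "_phase"),
                   units = "rad")
}

#' Rayleigh test p-value
#'
#' Standard approximation for the Rayleigh test of circular uniformity:
#' with `Z = n R^2`, `p = exp(-Z) * (1 + (2 Z - Z^2) / (4 n))`, clamped to
#' `[0, 1]`.
#'
#' @param n Number of angles.
#' @param r Resultant vector length in `[0, 1]`.
#' @return Approximate p-value.
#' @export
rayleigh_p <- function(n, r) {
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  min(max(p, 0), 1)
}

#' Spike-LFP phase-locking statistics
#'
#' Looks up the oscillation phase at each spike (nearest phase sample),
#' computes the circular mean angle and resultant vector length, and tests
#' uniformity with the Rayleigh test. Units with fewer than `min_spikes`
#' usable spikes return an insufficient-data row (`NA` statistics,
#' `significant = FALSE`) rather than failing silently.
#'
#' @param spikes A [spike_train()] (or numeric spike times).
#' @param phase A [signal_trace()] of instantaneous phase (radians; `NA`
#'   outside the analysed epochs).
#' @param restrict Optional [interval_set()]; spikes outside are dropped.
#' @param min_spikes Minimum spike count, default 10.
#' @param alpha Significance level, default 0.05.
#' @return A tibble (`phase_locking`) with `unit_id`, `n_spikes`,
#'   `mean_angle_deg` in `[0, 360)`, `resultant_length`, `rayleigh_p`,
#'   `significant`, `insufficient_data`.
#' @export
phase_locking_stats <- function(spikes, phase, restrict = NULL,
                                min_spikes = 10, alpha = 0.05) {
  st <- if (is.data.frame(spikes)) spikes$time_s else as.numeric(spikes)
  uid <- if (is.data.frame(spikes) && nrow(spikes)) spikes$unit_id[1] else "unit"
  stopifnot(inherits(phase, "signal_trace"))
  if (!is.null(restrict)) st <- st[interval_contains(restrict, st)]
  idx <- round((st - phase$t0) * phase$sample_rate) + 1
  ok <- idx >= 1 & idx <= length(phase$values)
  ph <- phase$values[idx[ok]]
  ph <- ph[!is.na(ph)]
  n <- length(ph)
  if (n < min_spikes) {
    out <- tibble::tibble(unit_id = uid, n_spikes = n,
                          mean_angle_deg = NA_real_,
                          resultant_length = NA_real_,
                          rayleigh_p = NA_real_, significant = FALSE,
                          insufficient_data = TRUE)
    class(out) <- c("phase_locking", class(out))
    return(out)
  }
  z <- mean(exp(1i * ph))
  r <- Mod(z)
  ang <- (Arg(z) * 180 / pi) %% 360
  p <- rayleigh_p(n, r)
  out <- tibble::tibble(unit_id = uid, n_spikes = n, mean_angle_deg = ang,
                        resultant_length = r, rayleigh_p = p,
                        significant = p < alpha, insufficient_data = FALSE)
  class(out) <- c("phase_locking", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.phase_locking <- function(x, ...) tibble::as_tibble(x)

#' Photo-identification of units from light responses
#'
#' Builds a trial-averaged peri-stimulus time histogram in 10 ms bins,
#' normalises each bin against the mean and SD of the 1 s pre-illumination
#' baseline, and classifies the unit as photo-responsive when the mean
#' z-score over the illumination window exceeds `z_crit` in magnitude
#' (direction from the sign). `rule = "any_bin"` instead classifies when any
#' single in-light bin crosses `z_crit` (more sensitive, much higher nominal
#' false-positive rate). Silent units (zero baseline SD) are flagged
#' unclassifiable.
#'
#' @param spikes A [spike_train()] or numeric spike times.
#' @param light_onsets Tibble of onset times (`time_s`) or numeric vector
#'   (>= 10 trials).
#' @param light_duration Illumination length (s), default 0.1.
#' @param baseline Baseline length before onset (s), default 1.
#' @param bin Bin width (s), default 0.01.
#' @param z_crit Classification threshold in z-units, default 1.96.
#' @param rule `"mean_z"` (default) or `"any_bin"`.
#' @return A `photo_id` object: list with `z_profile` (tibble: `time_s`,
#'   `rate_hz`, `z`), `statistic`, `classified`, `direction`,
#'   `unclassifiable`, `n_trials`.
#' @export
classify_photoresponse <- function(spikes, light_onsets, light_duration = 0.1,
                                   baseline = 1, bin = 0.01, z_crit = 1.96,
                                   rule = c("mean_z", "any_bin")) {
  rule <- match.arg(rule)
  st <- if (is.data.frame(spikes)) spikes$time_s else as.numeric(spikes)
  on <- if (is.data.frame(light_onsets)) light_onsets$time_s else as.numeric(light_onsets)
  if (length(on) < 10) stop("need at least 10 light trials", call. = FALSE)
  edges <- seq(-baseline, light_duration, by = bin)
  mids <- edges[-length(edges)] + bin / 2
  counts <- numeric(length(mids))
  for (t0 in on) {
    rel <- st[st >= t0 - baseline & st < t0 + light_duration] - t0
    if (length(rel)) {
      b <- findInterval(rel, edges, rightmost.closed = FALSE)
      b <- b[b >= 1 & b <= length(mids)]
      counts <- counts + tabulate(b, nbins = length(mids))
    }
  }
  rate <- counts / (length(on) * bin)
  base_sel <- mids < 0
  mu <- mean(rate[base_sel]); sd0 <- stats::sd(rate[base_sel])
  if (!is.finite(sd0) || sd0 == 0) {
    return(structure(
      list(z_profile = tibble::tibble(time_s = mids, rate_hz = rate,
                                      z = NA_real_),
           statistic = NA_real_, classified = FALSE, direction = "none",
           unclassifiable = TRUE, n_trials = length(on), rule = rule),
      class = "photo_id"))
  }
  z <- (rate - mu) / sd0
  light_sel <- mids >= 0
  stat <- if (rule == "mean_z") mean(z[light_sel]) else z[light_sel][which.max(abs(z[light_sel]))]
  classified <- abs(stat) > z_crit
  direction <- if (!classified) "none" else if (stat > 0) "increase" else "decrease"
  structure(
    list(z_profile = tibble::tibble(time_s = mids, rate_hz = rate, z = z),
         statistic = stat, classified = classified, direction = direction,
         unclassifiable = FALSE, n_trials = length(on), rule = rule),
    class = "photo_id")
}

#' @export
print.photo_id <- function(x, ...) {
  cat(sprintf("<photo_id> %s (statistic %.2f z, %d trials, rule %s)\n",
              if (x$unclassifiable) "unclassifiable"
              else if (x$classified) paste0("classified: ", x$direction)
              else "not classified",
              if (is.na(x$statistic)) NA else x$statistic,
              x$n_trials, x$rule))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.photo_id <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, classified = x$classified,
                 direction = x$direction, unclassifiable = x$unclassifiable,
                 n_trials = x$n_trials, rule = x$rule)
}
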