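#' @keywords internal
#' Zero-phase filtering with reflection padding.
#' signal::filtfilt alone leaves visible edge transients on long IIR filters;
#' reflecting ~1 s of signal at each end confines them to the padding.
filtfilt_padded <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 1000L)
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  y <- signal::filtfilt(filt, xp)
  y[seq(pad + 1, pad + n)]
}

#' Standardize a trace to z-units
#'
#' Centres and scales the whole trace to mean 0, variance 1. Applied to raw
#' LFP before notch filtering and detrending so that downstream amplitude
#' thresholds are scale-free.
#'
#' @param trace A [signal_trace()] with at least 2 samples and nonzero
#'   variance.
#' @return A [signal_trace()] in z-units; rate, origin and label preserved.
#' @export
standardize <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  if (length(trace$values) < 2) stop("trace needs >= 2 samples", call. = FALSE)
  s <- stats::sd(trace$values)
  if (!is.finite(s) || s == 0) stop("trace has zero variance; cannot standardize", call. = FALSE)
  signal_trace((trace$values - mean(trace$values)) / s,
               trace$sample_rate, trace$t0, trace$label, units = "z")
}

#' Notch filter for line noise
#'
#' Zero-phase (forward-backward) narrow band-stop centred on the mains
#' frequency. Realised as a 2nd-order Butterworth band-stop whose stop band
#' is `center/quality` wide; the transmission zero at `center` combined with
#' two-pass application gives > 30 dB rejection at the line frequency while
#' leaving physiological bands (e.g. 8 Hz theta, 100 Hz) within 1% of unity
#' gain.
#'
#' @param trace A [signal_trace()].
#' @param center Notch centre frequency (Hz), default 50.
#' @param quality Dimensionless quality factor (centre / bandwidth),
#'   default 30.
#' @return Filtered [signal_trace()].
#' @export
notch_filter <- function(trace, center = 50, quality = 30) {
  stopifnot(inherits(trace, "signal_trace"))
  nyq <- trace$sample_rate / 2
  if (center >= nyq) stop("notch `center` must be below the Nyquist frequency", call. = FALSE)
  bw <- center / quality
  edges <- c(center - bw / 2, center + bw / 2) / nyq
  filt <- signal::butter(2, edges, type = "stop")
  signal_trace(filtfilt_padded(filt, trace$values),
               trace$sample_rate, trace$t0, trace$label, trace$units)
}

#' Local-linear detrending
#'
#' Removes the slowly drifting DC component by fitting an ordinary
#' least-squares line within a sliding window (default 1 s every 0.5 s) and
#' subtracting a blended local fit. With 50% overlap every interior sample is
#' covered by two windows; their fits are cross-faded with triangular weights
#' (peaking at each window's centre) so the subtracted trend is continuous.
#' A globally linear input is removed to numerical precision; oscillations
#' well above 1/window Hz pass essentially untouched.
#'
#' @param trace A [signal_trace()] at least one window long.
#' @param window Window length (s), default 1.
#' @param step Window step (s), default 0.5.
#' @return Detrended [signal_trace()].
#' @export
detrend_local_linear <- function(trace, window = 1, step = 0.5) {
  stopifnot(inherits(trace, "signal_trace"))
  fs <- trace$sample_rate
  n <- length(trace$values)
  wlen <- round(window * fs)
  slen <- max(1L, round(step * fs))
  if (n < wlen) stop("trace shorter than one detrending window", call. = FALSE)
  x <- trace$values
  starts <- seq(1L, max(1L, n - wlen + 1L), by = slen)
  # make sure the tail is covered
  if (starts[length(starts)] + wlen - 1L < n) starts <- c(starts, n - wlen + 1L)
  trend_num <- numeric(n)
  trend_den <- numeric(n)
  tt <- seq_len(wlen) - (wlen + 1) / 2      # centred time index
  sxx <- sum(tt^2)
  tri <- 1 - abs(tt) / (wlen / 2)           # triangular weight, peak at centre
  tri <- pmax(tri, 1e-3)                    # keep window ends contributing
  for (s0 in starts) {
    idx <- s0:(s0 + wlen - 1L)
    seg <- x[idx]
    a <- mean(seg)
    b <- sum(tt * seg) / sxx
    fit <- a + b * tt
    trend_num[idx] <- trend_num[idx] + tri * fit
    trend_den[idx] <- trend_den[idx] + tri
  }
  trend <- trend_num / trend_den
  signal_trace(x - trend, fs, trace$t0, trace$label, trace$units)
}

#' Detect large low-frequency artifact intervals
#'
#' Computes the multitaper spectrogram (1 s window, 0.1 s step, 4 tapers by
#' default), takes the mean power in the artifact band (0.5-5 Hz), z-scores
#' that series across time, and returns the extents of all windows whose
#' z-score exceeds `z_threshold`. Intended for the large-amplitude transients
#' that contaminate chronic LFP recordings.
#'
#' Run detection on the standardized, notch-filtered signal *before*
#' local-linear detrending: the detrend stopband overlaps the artifact band
#' and suppresses exactly the slow transients this step must find. The
#' pipeline functions stage conditioning this way.
#'
#' @param trace A standardized (and typically notch-filtered)
#'   [signal_trace()].
#' @param band Length-2 Hz band to monitor, default `c(0.5, 5)`.
#' @param z_threshold Threshold on the z-scored band power, default 4.
#' @param window,step,n_tapers Spectrogram parameters (defaults 1 s, 0.1 s,
#'   4 tapers).
#' @return An [interval_set()] of window extents flagged as artifact
#'   (possibly empty).
#' @export
detect_artifact_intervals <- function(trace, band = c(0.5, 5), z_threshold = 4,
                                      window = 1, step = 0.1, n_tapers = 4) {
  stopifnot(inherits(trace, "signal_trace"))
  sg <- multitaper_spectrogram(trace, window = window, step = step,
                               n_tapers = n_tapers)
  fsel <- sg$freqs >= band[1] & sg$freqs <= band[2]
  if (!any(fsel)) return(interval_set())
  bp <- rowMeans(sg$values[, fsel, drop = FALSE])
  ok <- is.finite(bp)
  if (sum(ok) < 2 || stats::sd(bp[ok]) == 0) return(interval_set())
  z <- (bp - mean(bp[ok])) / stats::sd(bp[ok])
  hit <- which(ok & z > z_threshold)
  if (length(hit) == 0) return(interval_set())
  interval_set(sg$window_centers[hit] - window / 2,
               sg$window_centers[hit] + window / 2)
}

#' Peri-event exclusion mask
#'
#' Builds the union of `[t - pad, t + pad)` around each event time (e.g.
#' rewarding medial-forebrain-bundle stimulation), merged and clipped to the
#' recording span, for exclusion from spectral analysis.
#'
#' @param events Numeric vector of event times (s), or a tibble with a
#'   `time_s` column.
#' @param pad Half-width of the exclusion window (s), default 0.5.
#' @param total Optional [interval_set()] giving the admissible span to clip
#'   against.
#' @return An [interval_set()].
#' @export
build_exclusion_mask <- function(events, pad = 0.5, total = NULL) {
  t <- if (is.data.frame(events)) events$time_s else as.numeric(events)
  if (length(t) == 0) return(interval_set())
  m <- interval_set(t - pad, t + pad)
  if (!is.null(total)) m <- interval_intersect(m, total)
  m
}

#' Standard LFP conditioning chain
#'
#' Convenience wrapper applying the conditioning steps in their canonical
#' order: standardize, notch filter, local-linear detrend.
#'
#' @inheritParams standardize
#' @inheritParams notch_filter
#' @inheritParams detrend_local_linear
#' @return A conditioned [signal_trace()] in z-units.
#' @export
preprocess_lfp <- function(trace, center = 50, quality = 30,
                           window = 1, step = 0.5) {
  trace |>
    standardize() |>
    notch_filter(center = center, quality = quality) |>
    detrend_local_linear(window = window, step = step)
}
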