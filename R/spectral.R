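#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, as the top eigenvectors of the standard symmetric
#' tridiagonal commuting matrix. Tapers are returned with unit energy
#' (`colSums(v^2) == 1`), ordered by decreasing concentration, with the
#' conventional sign fix (symmetric tapers have positive mean; antisymmetric
#' tapers start positive).
#'
#' The default analysis uses `k = 4` tapers with `nw = 2.5`, following the
#' `k = 2*nw - 1` convention of the Chronux-style multitaper toolchain.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (> 0.5).
#' @param k Number of tapers (`1 <= k <= 2*nw - 1` recommended).
#' @return An `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 2.5, k = 4) {
  stopifnot(n >= 2, nw > 0.5, k >= 1, k < n)
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  cached <- .lfptheta_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  # dense symmetric eigendecomposition of the tridiagonal commuting matrix;
  # computed once per (n, nw, k) and cached
  m <- matrix(0, n, n)
  m[cbind(i + 1, i + 1)] <- diag_main
  m[cbind(1:(n - 1), 2:n)] <- diag_off
  m[cbind(2:n, 1:(n - 1))] <- diag_off
  eg <- eigen(m, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    vj <- v[, j]
    s <- sum(vj)
    if (abs(s) > 1e-8) {
      if (s < 0) v[, j] <- -vj
    } else if (vj[2] - vj[1] < 0) {
      v[, j] <- -vj
    }
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
  }
  assign(key, v, envir = .lfptheta_cache)
  v
}

.lfptheta_cache <- new.env(parent = emptyenv())

# internal unchecked constructor: band series etc. may carry NA for
# excluded windows
new_signal_trace <- function(values, sample_rate, t0 = 0, label = "", units = "") {
  structure(
    list(values = as.numeric(values), sample_rate = sample_rate, t0 = t0,
         label = label, units = units),
    class = "signal_trace"
  )
}

#' Time-frequency map container
#'
#' Window-centre-by-frequency matrix of power, coherence or imaginary
#' coherency, with the taper metadata needed to interpret it.
#'
#' @param window_centers Window-centre times (s).
#' @param freqs Frequency axis (Hz).
#' @param values `length(window_centers) x length(freqs)` matrix.
#' @param window_s,step_s,n_tapers Analysis parameters.
#' @param kind One of `"power"`, `"coherence"`, `"imaginary_coherency"`.
#' @return A `tf_map` object.
#' @export
tf_map <- function(window_centers, freqs, values, window_s, step_s, n_tapers,
                   kind = c("power", "coherence", "imaginary_coherency")) {
  kind <- match.arg(kind)
  stopifnot(nrow(values) == length(window_centers),
            ncol(values) == length(freqs))
  structure(
    list(window_centers = window_centers, freqs = freqs, values = values,
         window_s = window_s, step_s = step_s, n_tapers = n_tapers,
         kind = kind),
    class = "tf_map"
  )
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map:%s> %d windows x %d freqs (%g s window, %g s step, %d tapers)\n",
              x$kind, length(x$window_centers), length(x$freqs),
              x$window_s, x$step_s, x$n_tapers))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.tf_map <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$window_centers, times = length(x$freqs)),
    freq_hz = rep(x$freqs, each = length(x$window_centers)),
    value = as.vector(x$values),
    kind = x$kind
  )
}

# --- multitaper engine -------------------------------------------------------

# Window start indices (1-based) for a sliding analysis.
mt_window_starts <- function(n, wlen, slen) {
  if (n < wlen) stop("trace shorter than one analysis window", call. = FALSE)
  seq(1L, n - wlen + 1L, by = slen)
}

# Per-window multitaper auto/cross spectra, chunked to bound memory.
# Returns nwin x nfreq matrices: saa (+ sbb, sab when xb given).
mt_window_spectra <- function(xa, xb = NULL, fs, wlen, starts, tapers) {
  nfreq <- floor(wlen / 2) + 1L
  k <- ncol(tapers)
  nwin <- length(starts)
  saa <- matrix(0, nwin, nfreq)
  cross <- !is.null(xb)
  if (cross) {
    sbb <- matrix(0, nwin, nfreq)
    sab <- matrix(0 + 0i, nwin, nfreq)
  }
  one_sided <- rep(2, nfreq); one_sided[1] <- 1
  if (wlen %% 2 == 0) one_sided[nfreq] <- 1
  chunk <- 512L
  for (c0 in seq(1L, nwin, by = chunk)) {
    cs <- c0:min(nwin, c0 + chunk - 1L)
    idx <- outer(0:(wlen - 1L), starts[cs] - 1L, "+") + 1L
    sega <- matrix(xa[idx], nrow = wlen)
    if (cross) segb <- matrix(xb[idx], nrow = wlen)
    for (j in seq_len(k)) {
      fa <- stats::mvfft(sega * tapers[, j])[seq_len(nfreq), , drop = FALSE]
      saa[cs, ] <- saa[cs, ] + t(Re(fa * Conj(fa)))
      if (cross) {
        fb <- stats::mvfft(segb * tapers[, j])[seq_len(nfreq), , drop = FALSE]
        sbb[cs, ] <- sbb[cs, ] + t(Re(fb * Conj(fb)))
        sab[cs, ] <- sab[cs, ] + t(fa * Conj(fb))
      }
    }
  }
  # mean over tapers, one-sided density scaling (unit-energy tapers)
  sc <- matrix(one_sided / (k * fs), nwin, nfreq, byrow = TRUE)
  saa <- saa * sc
  if (cross) {
    sbb <- sbb * sc
    sab <- sab * sc
    list(saa = saa, sbb = sbb, sab = sab)
  } else {
    list(saa = saa)
  }
}

# Rows (windows) whose [start, end) span overlaps an exclusion interval set.
mt_excluded_rows <- function(t0, fs, wlen, starts, exclude) {
  if (is.null(exclude) || nrow(exclude) == 0) return(logical(length(starts)))
  ws <- t0 + (starts - 1) / fs
  we <- ws + wlen / fs
  out <- logical(length(starts))
  for (i in seq_len(nrow(exclude))) {
    out <- out | (ws < exclude$end[i] & we > exclude$start[i])
  }
  out
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper power spectral density: within each window the
#' periodograms of the DPSS-tapered segment are averaged over tapers. Power
#' is one-sided density in (signal units)^2/Hz, so the per-window integral
#' over frequency recovers the windowed signal variance. Windows overlapping
#' `exclude` are returned as `NA` rows.
#'
#' @param trace A [signal_trace()].
#' @param window Window length (s), default 1.
#' @param step Window step (s), default 0.1.
#' @param n_tapers Number of DPSS tapers, default 4 (time-bandwidth 2.5).
#' @param nw Time-bandwidth product, default `(n_tapers + 1) / 2`.
#' @param exclude Optional [interval_set()] of times to exclude.
#' @return A [tf_map()] of kind `"power"` (frequencies 0..Nyquist at
#'   `1/window` Hz resolution).
#' @export
multitaper_spectrogram <- function(trace, window = 1, step = 0.1, n_tapers = 4,
                                   nw = (n_tapers + 1) / 2, exclude = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  fs <- trace$sample_rate
  wlen <- round(window * fs)
  slen <- max(1L, round(step * fs))
  starts <- mt_window_starts(length(trace$values), wlen, slen)
  tapers <- dpss_tapers(wlen, nw = nw, k = n_tapers)
  sp <- mt_window_spectra(trace$values, fs = fs, wlen = wlen,
                          starts = starts, tapers = tapers)
  vals <- sp$saa
  bad <- mt_excluded_rows(trace$t0, fs, wlen, starts, exclude)
  vals[bad, ] <- NA_real_
  centers <- trace$t0 + (starts - 1 + wlen / 2) / fs
  freqs <- (seq_len(ncol(vals)) - 1) * fs / wlen
  tf_map(centers, freqs, vals, window, step, n_tapers, kind = "power")
}

#' Multitaper coherogram
#'
#' Sliding-window coherency between two equally sampled traces. Within each
#' window the taper-averaged cross-spectrum is normalised by the
#' taper-averaged auto-spectra; `mode = "magnitude"` returns
#' `|S_ab| / sqrt(S_aa S_bb)` and `mode = "imaginary"` the imaginary part of
#' the normalised coherency, which is insensitive to zero-lag
#' (volume-conducted) coupling.
#'
#' Note the per-window estimate has only `n_tapers` degrees of freedom, so
#' its magnitude has a substantial positive bias floor for independent
#' signals (see [coherence_bias_floor()]); use [coherence_spectrum()] for a
#' pooled low-bias estimate.
#'
#' @param a,b [signal_trace()] objects with identical rate and span.
#' @inheritParams multitaper_spectrogram
#' @param mode `"magnitude"` or `"imaginary"`.
#' @return A [tf_map()] of kind `"coherence"` or `"imaginary_coherency"`.
#' @export
multitaper_coherogram <- function(a, b, window = 1, step = 0.1, n_tapers = 4,
                                  nw = (n_tapers + 1) / 2, exclude = NULL,
                                  mode = c("magnitude", "imaginary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "signal_trace"), inherits(b, "signal_trace"))
  if (a$sample_rate != b$sample_rate || length(a$values) != length(b$values) ||
      abs(a$t0 - b$t0) > 1e-9) {
    stop("`a` and `b` must share sample rate, span and origin", call. = FALSE)
  }
  fs <- a$sample_rate
  wlen <- round(window * fs)
  slen <- max(1L, round(step * fs))
  starts <- mt_window_starts(length(a$values), wlen, slen)
  tapers <- dpss_tapers(wlen, nw = nw, k = n_tapers)
  sp <- mt_window_spectra(a$values, b$values, fs = fs, wlen = wlen,
                          starts = starts, tapers = tapers)
  coh <- sp$sab / sqrt(sp$saa * sp$sbb)
  vals <- if (mode == "magnitude") Mod(coh) else Im(coh)
  bad <- mt_excluded_rows(a$t0, fs, wlen, starts, exclude)
  vals[bad, ] <- NA_real_
  centers <- a$t0 + (starts - 1 + wlen / 2) / fs
  freqs <- (seq_len(ncol(vals)) - 1) * fs / wlen
  tf_map(centers, freqs, vals, window, step, n_tapers,
         kind = if (mode == "magnitude") "coherence" else "imaginary_coherency")
}

#' Pooled coherence spectrum
#'
#' Coherency estimated by pooling taper cross- and auto-spectra over all
#' retained windows, giving `n_windows * n_tapers` degrees of freedom per
#' frequency. This is the appropriate estimator for a session-mean coherence
#' spectrum: its bias floor for independent signals shrinks as
#' `~ sqrt(pi) / (2 sqrt(dof))` (see [coherence_bias_floor()]).
#'
#' @inheritParams multitaper_coherogram
#' @param squared Return magnitude-squared coherence instead of magnitude
#'   (default `FALSE`: magnitude).
#' @return A tibble with columns `freq_hz`, `coherence`, `imaginary`,
#'   `n_windows`, `n_tapers`.
#' @export
coherence_spectrum <- function(a, b, window = 1, step = 0.1, n_tapers = 4,
                               nw = (n_tapers + 1) / 2, exclude = NULL,
                               squared = FALSE) {
  stopifnot(inherits(a, "signal_trace"), inherits(b, "signal_trace"))
  if (a$sample_rate != b$sample_rate || length(a$values) != length(b$values)) {
    stop("`a` and `b` must share sample rate and span", call. = FALSE)
  }
  fs <- a$sample_rate
  wlen <- round(window * fs)
  slen <- max(1L, round(step * fs))
  starts <- mt_window_starts(length(a$values), wlen, slen)
  tapers <- dpss_tapers(wlen, nw = nw, k = n_tapers)
  bad <- mt_excluded_rows(a$t0, fs, wlen, starts, exclude)
  starts <- starts[!bad]
  if (length(starts) == 0) stop("no analysis windows survive the exclusion mask", call. = FALSE)
  sp <- mt_window_spectra(a$values, b$values, fs = fs, wlen = wlen,
                          starts = starts, tapers = tapers)
  sab <- colSums(sp$sab)
  saa <- colSums(sp$saa)
  sbb <- colSums(sp$sbb)
  coh <- sab / sqrt(saa * sbb)
  mag <- Mod(coh)
  tibble::tibble(
    freq_hz = (seq_along(mag) - 1) * fs / wlen,
    coherence = if (squared) mag^2 else mag,
    imaginary = Im(coh),
    n_windows = length(starts),
    n_tapers = n_tapers
  )
}

#' Analytic magnitude-coherence bias floor for independent signals
#'
#' For two independent Gaussian signals, the magnitude-coherence estimate
#' built from `m` independent (window x taper) cross-spectral samples has
#' `|C|^2 ~ Beta(1, m - 1)`, whence `E|C| = sqrt(pi)/2 * Gamma(m) /
#' Gamma(m + 1/2)`. With the default 4 tapers per window this floor is
#' about 0.46 for per-window coherograms, and shrinks as `1/sqrt(m)` for
#' pooled estimates.
#'
#' @param m Degrees of freedom (number of independent cross-spectral
#'   samples, i.e. windows x tapers).
#' @return Expected magnitude coherence under independence.
#' @export
coherence_bias_floor <- function(m) {
  stopifnot(all(m >= 1))
  sqrt(pi) / 2 * exp(lgamma(m) - lgamma(m + 0.5))
}

#' Extract a band-average series from a time-frequency map
#'
#' Per-window mean over the frequency bins falling in `[f_lo, f_hi]`,
#' returned on the window-centre grid (10 Hz for the default 0.1 s step).
#' `NA` windows (exclusions) propagate.
#'
#' @param map A [tf_map()].
#' @param band Length-2 numeric `(f_lo, f_hi)` in Hz, or a row of
#'   [band_table()].
#' @return A [signal_trace()] on the window-centre grid (may contain `NA`
#'   at excluded windows).
#' @export
band_series <- function(map, band) {
  stopifnot(inherits(map, "tf_map"))
  if (is.data.frame(band)) band <- c(band$f_lo[1], band$f_hi[1])
  stopifnot(length(band) == 2, band[1] < band[2])
  fsel <- map$freqs >= band[1] & map$freqs <= band[2]
  if (!any(fsel)) stop("band does not intersect the map's frequency axis", call. = FALSE)
  v <- rowMeans(map$values[, fsel, drop = FALSE], na.rm = FALSE)
  # masked line-noise bins inside the band should not poison the average
  if (anyNA(map$values[, fsel]) ) {
    sub <- map$values[, fsel, drop = FALSE]
    all_na <- rowSums(!is.na(sub)) == 0
    v <- rowMeans(sub, na.rm = TRUE)
    v[all_na] <- NA_real_
  }
  new_signal_trace(v, sample_rate = 1 / map$step_s, t0 = map$window_centers[1],
                   label = sprintf("band_%g_%g", band[1], band[2]),
                   units = map$kind)
}

#' Time-averaged spectrum of a spectrogram
#'
#' @param map A [tf_map()] of kind `"power"`.
#' @return Tibble with `freq_hz`, `power` (mean over retained windows).
#' @export
mean_spectrum <- function(map) {
  stopifnot(inherits(map, "tf_map"))
  tibble::tibble(freq_hz = map$freqs,
                 power = colMeans(map$values, na.rm = TRUE))
}

#' Z-score a power spectrum across frequency
#'
#' Standardises the time-averaged spectral power across the frequency bins in
#' `range` (default 0.1-500 Hz) to homogenise values across animals and
#' regions. A flat spectrum yields all zeros (not an error); output is
#' invariant to positive rescaling of the input.
#'
#' @param spectrum Tibble with columns `freq_hz` and `power` (as from
#'   [mean_spectrum()]), or a numeric vector with `freqs` supplied.
#' @param range Frequency range (Hz) over which to standardise.
#' @param freqs Frequency axis when `spectrum` is a bare vector.
#' @return Tibble with `freq_hz` and `z` for bins inside `range`.
#' @export
zscore_power_spectrum <- function(spectrum, range = c(0.1, 500), freqs = NULL) {
  if (is.data.frame(spectrum)) {
    f <- spectrum$freq_hz; p <- spectrum$power
  } else {
    f <- freqs; p <- as.numeric(spectrum)
  }
  sel <- f >= range[1] & f <= range[2] & is.finite(p)
  if (sum(sel) < 2) stop("need >= 2 frequency bins in range", call. = FALSE)
  ps <- p[sel]
  s <- stats::sd(ps)
  z <- if (s == 0) rep(0, length(ps)) else (ps - mean(ps)) / s
  tibble::tibble(freq_hz = f[sel], z = z)
}

#' Mask the line-noise band
#'
#' Marks values in the (open) band as missing — the notch filter leaves a
#' spurious structure around the mains frequency, so those bins are excluded
#' from coherence displays and from any later band averaging. Band edges are
#' exclusive so that a low-gamma band ending exactly at the lower edge is
#' unaffected. Idempotent.
#'
#' @param x A [tf_map()] or a spectrum tibble with `freq_hz`.
#' @param band Length-2 Hz band, default `c(48, 52)`.
#' @return Same type as `x` with in-band values `NA`.
#' @export
mask_line_band <- function(x, band = c(48, 52)) {
  if (inherits(x, "tf_map")) {
    sel <- x$freqs > band[1] & x$freqs < band[2]
    x$values[, sel] <- NA_real_
    return(x)
  }
  if (is.data.frame(x)) {
    sel <- x$freq_hz > band[1] & x$freq_hz < band[2]
    vcols <- setdiff(names(x), "freq_hz")
    x[sel, vcols] <- NA
    return(x)
  }
  stop("unsupported input to mask_line_band", call. = FALSE)
}

#' Pool a distance profile over a distance window
#'
#' Occupancy-weighted mean of a profile's values over the distance bins in
#' `distance_window` (default the approach segment −60 to −20 cm from
#' reward), optionally restricted to a frequency band when the profile is
#' frequency-resolved.
#'
#' @param profile A [distance_profile()] tibble.
#' @param distance_window Length-2 cm window (negative = before reward).
#' @param band Optional length-2 Hz band (or [band_table()] row) when
#'   `profile` has a `freq_hz` column.
#' @return A single number, or `NA` (with a warning) if no occupied bins
#'   fall in the window.
#' @export
pool_profile <- function(profile, distance_window = c(-60, -20), band = NULL) {
  stopifnot(is.data.frame(profile))
  d <- profile[profile$bin_center_cm >= distance_window[1] &
                 profile$bin_center_cm <= distance_window[2], , drop = FALSE]
  if (!is.null(band) && "freq_hz" %in% names(d)) {
    if (is.data.frame(band)) band <- c(band$f_lo[1], band$f_hi[1])
    d <- d[d$freq_hz >= band[1] & d$freq_hz <= band[2], , drop = FALSE]
  }
  d <- d[is.finite(d$value) & d$occupancy_s > 0, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no occupied bins in the pooling window")
    return(NA_real_)
  }
  sum(d$value * d$occupancy_s) / sum(d$occupancy_s)
}

#' Average a quantity across hemispheres
#'
#' Element-wise mean of left- and right-hemisphere results when both
#' electrodes were on target; pass-through when one is missing (`NULL` or
#' all-`NA`).
#'
#' @param left,right Scalars, vectors, matrices or [tf_map()]s of matching
#'   shape; either may be `NULL`.
#' @return Same type as the inputs, or `NA` if both are missing.
#' @export
average_hemispheres <- function(left = NULL, right = NULL) {
  missing_l <- is.null(left)
  missing_r <- is.null(right)
  if (missing_l && missing_r) return(NA)
  if (missing_l) return(right)
  if (missing_r) return(left)
  if (inherits(left, "tf_map")) {
    stopifnot(inherits(right, "tf_map"),
              identical(dim(left$values), dim(right$values)))
    left$values <- (left$values + right$values) / 2
    return(left)
  }
  if (is.data.frame(left)) {
    out <- left
    num <- vapply(left, is.numeric, logical(1)) &
      vapply(right, is.numeric, logical(1))
    num["freq_hz" == names(left)] <- FALSE
    out[num] <- (left[num] + right[num]) / 2
    return(out)
  }
  (left + right) / 2
}

#' Canonical frequency-band table
#'
#' Delta 2-4, theta 6-12, beta 13-29 and low-gamma 30-48 Hz.
#'
#' @return Tibble with `band`, `f_lo`, `f_hi`.
#' @export
band_table <- function() {
  tibble::tibble(
    band = c("delta", "theta", "beta", "low_gamma"),
    f_lo = c(2, 6, 13, 30),
    f_hi = c(4, 12, 29, 48)
  )
}
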