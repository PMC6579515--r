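# Shared fixtures, all generated in code.

white_trace <- function(n, fs = 1000, seed = 1, label = "white") {
  set.seed(seed)
  signal_trace(stats::rnorm(n), fs, label = label)
}

sine_trace <- function(freq, dur = 10, fs = 1000, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  signal_trace(amp * sin(2 * pi * freq * t + phase), fs)
}

# independent per-sample scan oracle for active-epoch detection
brute_force_epochs <- function(speed_values, fs, t0, threshold, min_dur) {
  above <- speed_values > threshold
  starts <- c(); ends <- c()
  i <- 1; n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if ((j - i + 1) / fs >= min_dur) {
        starts <- c(starts, t0 + (i - 1) / fs)
        ends <- c(ends, t0 + j / fs)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (length(starts) == 0) interval_set() else interval_set(starts, ends)
}

# membership oracle on a fine sample grid
sample_mask_oracle <- function(iv, times) {
  out <- rep(FALSE, length(times))
  for (k in seq_len(nrow(iv))) {
    out <- out | (times >= iv$start[k] & times < iv$end[k])
  }
  out
}

three_channel_spec <- function(targets = c(crusI = 0.35, lobII_III = 0.10),
                               ...) {
  session_spec(
    channels = tibble::tibble(
      label = c("hpc_left", "crusI", "lobII_III"),
      role = c("hippocampus_left", "crusI", "lobII_III")),
    coherence_targets = tibble::tibble(
      chan_a = "hpc_left", chan_b = names(targets),
      target = unname(targets)),
    ...)
}
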