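# Evaluate expr under a given seed without disturbing the caller's RNG state.
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Session specification for the synthetic generator
#'
#' Collects the generating parameters of one synthetic recording session:
#' channel layout, in-band (theta) coherence targets, line-noise and artifact
#' contamination, and the behavioural paradigm. Defaults mirror the recording
#' conditions the analysis assumes: 1 kHz LFP, 30 Hz tracking, a 1 m linear
#' track with 5 cm goal zones 10 cm from each end, 12-min sessions.
#'
#' Coherence targets are interpreted against a single shared theta source:
#' the first hippocampal channel is the reference (its in-band content is the
#' source itself), and each other channel mixes the source with independent
#' theta-shaped noise at its target level. Consequently the implied coherence
#' between two non-reference channels is the product of their targets; an
#' explicit target for such a pair that is inconsistent with this
#' single-source model (by more than 0.05) is rejected as non-realizable.
#'
#' @param duration Session length (s), default 720 (12 min).
#' @param sample_rate LFP sampling rate (Hz), default 1000.
#' @param channels Tibble with columns `label`, `role`; roles in
#'   `hippocampus_left`, `hippocampus_right`, `crusI`, `lobVI`, `lobII_III`.
#' @param coherence_targets Tibble with columns `chan_a`, `chan_b`, `target`
#'   (theta-band magnitude coherence in `[0, 1]`).
#' @param theta_band Length-2 Hz band carrying the shared source, default
#'   `c(6, 12)`.
#' @param line_noise_amplitude 50 Hz sinusoid amplitude in signal SD units,
#'   default 0.2.
#' @param artifact_rate Large low-frequency transients per minute, default 0.
#' @param behavior_mode `"homecage"` or `"linear_track"`.
#' @param behavior_profile For the linear track: `"goal_directed"`
#'   (accelerate-plateau-decelerate runs) or `"exploratory"` (slow, variable,
#'   with turnarounds).
#' @param track_length Track length (cm), default 100.
#' @param goal_zone_width Goal-zone width (cm), default 5.
#' @param goal_zone_offset Distance of the zone from the track end (cm),
#'   default 10.
#' @param units Tibble of spiking units to simulate: columns `unit_id`,
#'   `base_rate` (Hz), `kappa`, `mu_deg` (preferred theta phase).
#' @param seed Integer master seed; all sub-streams derive from it.
#' @return A `session_spec` list.
#' @export
session_spec <- function(duration = 720,
                         sample_rate = 1000,
                         channels = default_channels(),
                         coherence_targets = NULL,
                         theta_band = c(6, 12),
                         line_noise_amplitude = 0.2,
                         artifact_rate = 0,
                         behavior_mode = c("homecage", "linear_track"),
                         behavior_profile = c("goal_directed", "exploratory"),
                         track_length = 100,
                         goal_zone_width = 5,
                         goal_zone_offset = 10,
                         units = NULL,
                         seed = 1L) {
  behavior_mode <- match.arg(behavior_mode)
  behavior_profile <- match.arg(behavior_profile)
  stopifnot(duration > 0, sample_rate > 0,
            is.data.frame(channels), all(c("label", "role") %in% names(channels)),
            !anyDuplicated(channels$label),
            theta_band[1] < theta_band[2], theta_band[1] > 0,
            line_noise_amplitude >= 0, artifact_rate >= 0,
            track_length > 0, goal_zone_width > 0, goal_zone_offset >= 0,
            goal_zone_offset + goal_zone_width <= track_length / 2)
  if (is.null(coherence_targets)) {
    coherence_targets <- tibble::tibble(chan_a = character(0),
                                        chan_b = character(0),
                                        target = numeric(0))
  }
  stopifnot(all(coherence_targets$target >= 0),
            all(coherence_targets$target <= 1),
            all(coherence_targets$chan_a %in% channels$label),
            all(coherence_targets$chan_b %in% channels$label))
  structure(
    list(duration = duration, sample_rate = sample_rate, channels = channels,
         coherence_targets = coherence_targets, theta_band = theta_band,
         line_noise_amplitude = line_noise_amplitude,
         artifact_rate = artifact_rate, behavior_mode = behavior_mode,
         behavior_profile = behavior_profile, track_length = track_length,
         goal_zone_width = goal_zone_width, goal_zone_offset = goal_zone_offset,
         units = units, seed = as.integer(seed)),
    class = "session_spec"
  )
}

#' Default channel layout
#' @return Tibble of the five standard channels (two hippocampal, three
#'   cerebellar).
#' @export
default_channels <- function() {
  tibble::tibble(
    label = c("hpc_left", "hpc_right", "crusI", "lobVI", "lobII_III"),
    role = c("hippocampus_left", "hippocampus_right", "crusI", "lobVI",
             "lobII_III")
  )
}

# LFP-like one-sided power profile on the full FFT frequency grid:
# pink background plus a Gaussian theta bump whose height depends on region.
lfp_power_profile <- function(freqs_abs, theta_gain, theta_center = 8,
                              theta_sd = 1.2) {
  base <- 1 / (1 + freqs_abs)
  bump <- theta_gain * exp(-(freqs_abs - theta_center)^2 / (2 * theta_sd^2))
  base + bump
}

# Shape white noise in the frequency domain: returns a real Gaussian signal
# with PSD proportional to amp_profile^2 (amp given on the full fft grid).
shape_noise <- function(n, amp_profile) {
  z <- stats::rnorm(n)
  Re(stats::fft(stats::fft(z) * amp_profile, inverse = TRUE)) / n
}

#' Generate a pair of signals with known flat coherence
#'
#' Draws a stationary LFP-like signal `x` and an independent noise signal
#' `n` with the same spectral shape, rescales both to unit variance, and
#' returns `(x, y)` with `y = target * x' + sqrt(1 - target^2) * n'`. Under
#' this equal-spectrum mixing the population magnitude coherence between `x`
#' and `y` equals `target` at every frequency, giving an exact oracle for
#' coherence estimators.
#'
#' @param n_samples Number of samples.
#' @param sample_rate Sampling rate (Hz).
#' @param target Population coherence in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with elements `x` and `y`, both [signal_trace()]s.
#' @export
generate_coherent_pair <- function(n_samples, sample_rate, target, seed = 1L) {
  if (!is.numeric(target) || length(target) != 1 || target < 0 || target > 1) {
    stop("`target` must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(n_samples >= 16)
  with_seed_local(seed, {
    freqs <- fft_freqs(n_samples, sample_rate)
    amp <- sqrt(lfp_power_profile(abs(freqs), theta_gain = 3))
    x <- shape_noise(n_samples, amp)
    nse <- shape_noise(n_samples, amp)
    x <- x / stats::sd(x)
    nse <- nse / stats::sd(nse)
    y <- target * x + sqrt(1 - target^2) * nse
    list(x = signal_trace(x, sample_rate, label = "x", units = "a.u."),
         y = signal_trace(y, sample_rate, label = "y", units = "a.u."))
  })
}

# absolute frequency of each FFT bin (full grid, Hz)
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]
  f
}

#' Generate von Mises phase-locked spike trains
#'
#' Simulates an inhomogeneous point process whose intensity is modulated by
#' an oscillation phase: `lambda(t) = base_rate * exp(kappa * cos(phase(t) -
#' mu)) / I0(kappa)`, so the time-averaged rate is approximately `base_rate`
#' when the phase is uniformly distributed over time, and `kappa = 0` reduces
#' to a homogeneous process. Samples per-bin Bernoulli events at the phase
#' series' rate with sub-sample jitter.
#'
#' @param phase A [signal_trace()] of instantaneous phase (radians), or a
#'   numeric vector with `sample_rate` given.
#' @param base_rate Mean firing rate (Hz, > 0).
#' @param kappa von Mises concentration (>= 0).
#' @param mu Preferred phase (radians).
#' @param seed Integer seed.
#' @param sample_rate Rate of `phase` when it is a bare vector.
#' @param unit_id Label for the output train.
#' @return A tibble (`spike_train`) with columns `unit_id`, `time_s`.
#' @export
generate_phase_locked_spikes <- function(phase, base_rate, kappa = 0, mu = 0,
                                         seed = 1L, sample_rate = NULL,
                                         unit_id = "unit1") {
  if (inherits(phase, "signal_trace")) {
    ph <- phase$values; fs <- phase$sample_rate; t0 <- phase$t0
  } else {
    ph <- as.numeric(phase); fs <- sample_rate; t0 <- 0
    if (is.null(fs)) stop("supply `sample_rate` with a bare phase vector", call. = FALSE)
  }
  if (!is.numeric(base_rate) || base_rate <= 0) {
    stop("`base_rate` must be positive", call. = FALSE)
  }
  stopifnot(kappa >= 0)
  with_seed_local(seed, {
    lambda <- base_rate * exp(kappa * cos(ph - mu)) / besselI(kappa, 0)
    lambda[is.na(lambda)] <- 0
    p <- lambda / fs
    if (any(p > 1, na.rm = TRUE)) {
      warning("per-bin spike probability exceeds 1; rate effectively capped")
      p <- pmin(p, 1)
    }
    hit <- which(stats::runif(length(p)) < p)
    times <- t0 + (hit - 1) / fs + stats::runif(length(hit)) / fs
    spike_train(unit_id, sort(times))
  })
}

#' Spike train container
#' @param unit_id Unit label.
#' @param times Strictly increasing spike times (s).
#' @return Tibble of class `spike_train` with `unit_id`, `time_s`.
#' @export
spike_train <- function(unit_id, times) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = FALSE)) stop("spike times must be sorted", call. = FALSE)
  out <- tibble::tibble(unit_id = unit_id, time_s = times)
  class(out) <- c("spike_train", class(out))
  out
}

#' Tracking trace container
#' @param time_s,x_cm,y_cm Position samples; times strictly increasing.
#' @param source_rate Nominal tracker rate (Hz).
#' @return Tibble of class `tracking_trace`.
#' @export
tracking_trace <- function(time_s, x_cm, y_cm = rep(0, length(time_s)),
                           source_rate = 30) {
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("tracking times must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time_s = time_s, x_cm = x_cm, y_cm = y_cm)
  attr(out, "source_rate") <- source_rate
  class(out) <- c("tracking_trace", class(out))
  out
}

#' Generate behaviour for a synthetic session
#'
#' Home-cage mode simulates bout-structured 2-D exploration (alternating
#' movement and rest states) whose speed distribution straddles the 3 cm/s
#' activity threshold; no rewards are delivered. Linear-track mode simulates
#' back-and-forth 1-D runs between the two goal zones, with either an
#' exploratory profile (slow, variable, occasional mid-track turnarounds) or
#' a goal-directed accelerate-plateau-decelerate profile; a reward event is
#' emitted at the moment the animal enters the upcoming goal zone.
#'
#' @param spec A [session_spec()].
#' @return List with `tracking` (a [tracking_trace()]) and `events` (tibble
#'   of reward times, empty for home cage).
#' @export
generate_behavior <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  seed_b <- with_seed_local(spec$seed, sample.int(.Machine$integer.max, 3))[2]
  with_seed_local(seed_b, {
    if (spec$behavior_mode == "homecage") {
      generate_homecage_behavior(spec)
    } else {
      generate_track_behavior(spec)
    }
  })
}

generate_homecage_behavior <- function(spec, box = 40) {
  fr <- 30
  n <- floor(spec$duration * fr)
  dt <- 1 / fr
  # alternating move / rest bouts
  state_speed <- numeric(n)
  i <- 1L
  moving <- stats::runif(1) < 0.5
  while (i <= n) {
    len <- max(2L, round(stats::rexp(1, rate = if (moving) 1 / 20 else 1 / 10) * fr))
    j <- min(n, i + len - 1L)
    base <- if (moving) stats::runif(1, 5, 10) else stats::runif(1, 0.1, 1)
    state_speed[i:j] <- base
    i <- j + 1L
    moving <- !moving
  }
  sp <- pmax(0, state_speed + stats::rnorm(n, 0, 0.5))
  heading <- cumsum(stats::rnorm(n, 0, 0.4))
  x <- numeric(n); y <- numeric(n)
  x[1] <- box / 2; y[1] <- box / 2
  for (t in 2:n) {
    x[t] <- x[t - 1] + sp[t] * cos(heading[t]) * dt
    y[t] <- y[t - 1] + sp[t] * sin(heading[t]) * dt
    if (x[t] < 0 || x[t] > box) { heading[t:n] <- pi - heading[t:n]; x[t] <- min(max(x[t], 0), box) }
    if (y[t] < 0 || y[t] > box) { heading[t:n] <- -heading[t:n]; y[t] <- min(max(y[t], 0), box) }
  }
  list(tracking = tracking_trace((seq_len(n) - 1) * dt, x, y, source_rate = fr),
       events = tibble::tibble(time_s = numeric(0)))
}

generate_track_behavior <- function(spec) {
  fr <- 30
  dt <- 1 / fr
  n <- floor(spec$duration * fr)
  L <- spec$track_length
  zone_lo <- c(spec$goal_zone_offset,
               L - spec$goal_zone_offset - spec$goal_zone_width)
  zone_hi <- zone_lo + spec$goal_zone_width
  goal_center <- (zone_lo + zone_hi) / 2
  goal_directed <- spec$behavior_profile == "goal_directed"
  x <- numeric(n)
  rewards <- numeric(0)
  pos <- goal_center[1]
  target <- 2L                     # run toward the far zone first
  t <- 1L
  x[1] <- pos
  pause_left <- 0
  v <- 0
  turn_left <- 0                   # remaining turnaround samples (exploratory)
  vmax <- if (goal_directed) stats::runif(1, 20, 30) else stats::runif(1, 5, 9)
  accel <- 30
  while (t < n) {
    t <- t + 1L
    if (pause_left > 0) {
      pause_left <- pause_left - 1L
      x[t] <- pos + stats::rnorm(1, 0, 0.05)
      next
    }
    dir <- sign(goal_center[target] - pos)
    if (!goal_directed) {
      if (turn_left > 0) {
        dir <- -dir
        turn_left <- turn_left - 1L
      } else if (stats::runif(1) < 0.004 &&
                 abs(goal_center[target] - pos) > 20) {
        turn_left <- round(stats::runif(1, 1, 3) * fr)
      }
      v <- max(3.2, vmax + stats::rnorm(1, 0, 1.5))
    } else {
      d_rem <- abs(goal_center[target] - pos)
      v_brake <- sqrt(2 * accel * max(d_rem, 0)) + 2
      v <- min(vmax + stats::rnorm(1, 0, 0.8), v + accel * dt, v_brake)
      v <- max(v, 2)
    }
    pos <- pos + dir * v * dt
    pos <- min(max(pos, 0), L)
    x[t] <- pos
    in_target <- pos >= zone_lo[target] && pos < zone_hi[target]
    if (in_target) {
      rewards <- c(rewards, (t - 1) * dt)
      target <- 3L - target
      pause_left <- round(stats::runif(1, if (goal_directed) 1 else 2,
                                       if (goal_directed) 2 else 4) * fr)
      v <- 0
      vmax <- if (goal_directed) stats::runif(1, 20, 30) else stats::runif(1, 5, 9)
    }
  }
  list(tracking = tracking_trace((seq_len(n) - 1) * dt, x,
                                 rep(0, n), source_rate = fr),
       events = tibble::tibble(time_s = rewards))
}

#' Generate a full synthetic session
#'
#' Builds a multi-channel LFP set with exact in-band ground-truth coherence
#' (single shared theta source, per-channel frequency-domain mixing),
#' region-appropriate spectral shapes (strong hippocampal theta bump, weak
#' cerebellar one), 50 Hz line contamination, injected low-frequency
#' artifact bursts, behaviour, and optional von Mises phase-locked spike
#' trains referenced to the theta source phase. The returned bundle carries a
#' `ground_truth` record (targets, artifact intervals, source phase, unit
#' parameters) for validation.
#'
#' @param spec A [session_spec()].
#' @return A `session_bundle`: list with `signals` (named [signal_trace()]s),
#'   `tracking`, `events` (named list of tibbles), `spikes` (named list of
#'   [spike_train()]s), `metadata`, and `ground_truth`.
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  seeds <- with_seed_local(spec$seed, sample.int(.Machine$integer.max, 5))
  fs <- spec$sample_rate
  n <- floor(spec$duration * fs)
  ch <- spec$channels
  ref <- ch$label[ch$role == "hippocampus_left"][1]
  if (is.na(ref)) ref <- ch$label[1]

  # per-channel mixing coefficient against the shared theta source
  cvec <- stats::setNames(rep(0, nrow(ch)), ch$label)
  cvec[ref] <- 1
  tg <- spec$coherence_targets
  defaults_hr <- ch$label[ch$role == "hippocampus_right"]
  if (length(defaults_hr)) cvec[defaults_hr] <- 0.9
  if (nrow(tg)) {
    for (i in seq_len(nrow(tg))) {
      pair <- c(tg$chan_a[i], tg$chan_b[i])
      if (ref %in% pair) {
        other <- setdiff(pair, ref)
        cvec[other] <- tg$target[i]
      }
    }
    # non-reference pairs must be consistent with the single-source model
    for (i in seq_len(nrow(tg))) {
      pair <- c(tg$chan_a[i], tg$chan_b[i])
      if (!(ref %in% pair)) {
        implied <- cvec[pair[1]] * cvec[pair[2]]
        if (abs(implied - tg$target[i]) > 0.05) {
          stop(sprintf(paste0(
            "coherence target %s-%s = %.2f is not realizable under the ",
            "single-source model (implied %.2f = product of the two ",
            "reference targets); specify targets against the reference ",
            "channel '%s'"), pair[1], pair[2], tg$target[i], implied, ref),
            call. = FALSE)
        }
      }
    }
  }

  freqs <- fft_freqs(n, fs)
  in_band <- freqs >= spec$theta_band[1] & freqs <= spec$theta_band[2]
  signals <- list()
  theta_phase <- NULL
  with_seed_local(seeds[1], {
    u <- stats::fft(stats::rnorm(n))          # shared source coefficients
    for (i in seq_len(nrow(ch))) {
      lab <- ch$label[i]
      hip <- grepl("hippocampus", ch$role[i])
      amp <- sqrt(lfp_power_profile(freqs, theta_gain = if (hip) 6 else 0.8))
      v <- stats::fft(stats::rnorm(n))        # channel-private coefficients
      cj <- cvec[lab]
      coef <- amp * ifelse(in_band, cj * u + sqrt(1 - cj^2) * v, v)
      xi <- Re(stats::fft(coef, inverse = TRUE)) / n
      xi <- xi / stats::sd(xi)
      signals[[lab]] <- signal_trace(xi, fs, t0 = 0, label = lab, units = "a.u.")
      if (lab == ref) {
        # analytic signal of the reference's in-band source component: the
        # generating theta phase, independent of any analysis-side filter
        coef_band <- amp * in_band * u
        pos <- seq_len(n) - 1 < n / 2
        onesided <- coef_band * ifelse(pos, 2, 0)
        onesided[1] <- coef_band[1]
        analytic <- stats::fft(onesided, inverse = TRUE) / n
        theta_phase <- new_signal_trace(Arg(analytic), fs, 0,
                                        label = "theta_phase", units = "rad")
      }
    }
  })

  # 50 Hz line noise, common phase across channels (volume conducted)
  if (spec$line_noise_amplitude > 0) {
    tt <- (seq_len(n) - 1) / fs
    line_phi <- with_seed_local(seeds[5], stats::runif(1, 0, 2 * pi))
    line <- spec$line_noise_amplitude * sin(2 * pi * 50 * tt + line_phi)
    for (lab in names(signals)) {
      signals[[lab]]$values <- signals[[lab]]$values + line
    }
  }

  # large 0.5-5 Hz Gaussian-windowed bursts, common to all channels
  artifact_iv <- interval_set()
  if (spec$artifact_rate > 0) {
    artifact_iv <- with_seed_local(seeds[3], {
      n_art <- stats::rpois(1, spec$artifact_rate * spec$duration / 60)
      ss <- numeric(0); ee <- numeric(0)
      if (n_art > 0) {
        centers <- sort(stats::runif(n_art, 2, spec$duration - 2))
        tt <- (seq_len(n) - 1) / fs
        for (tc in centers) {
          dur <- stats::runif(1, 0.4, 1)
          sigma <- dur / 4
          f_a <- stats::runif(1, 0.5, 5)
          amp <- stats::runif(1, 10, 20)
          sel <- which(abs(tt - tc) < 3 * sigma)
          burst <- amp * exp(-(tt[sel] - tc)^2 / (2 * sigma^2)) *
            cos(2 * pi * f_a * (tt[sel] - tc))
          for (lab in names(signals)) {
            signals[[lab]]$values[sel] <- signals[[lab]]$values[sel] + burst
          }
          # ground truth marks the energetic core (envelope >= 13.5% of
          # peak); the faint Gaussian tails beyond 2 sigma are undetectable
          # by construction
          ss <- c(ss, tc - 2 * sigma); ee <- c(ee, tc + 2 * sigma)
        }
      }
      interval_set(ss, ee)
    })
  }

  behav <- generate_behavior(spec)

  spikes <- list()
  if (!is.null(spec$units) && nrow(spec$units) > 0 && !is.null(theta_phase)) {
    sub <- with_seed_local(seeds[4],
                           sample.int(.Machine$integer.max, nrow(spec$units)))
    for (i in seq_len(nrow(spec$units))) {
      u_row <- spec$units[i, ]
      spikes[[u_row$unit_id]] <- generate_phase_locked_spikes(
        theta_phase, base_rate = u_row$base_rate, kappa = u_row$kappa,
        mu = u_row$mu_deg * pi / 180, seed = sub[i], unit_id = u_row$unit_id)
    }
  }

  structure(
    list(
      signals = signals,
      tracking = behav$tracking,
      events = list(reward = behav$events),
      spikes = spikes,
      metadata = list(
        subject = "synthetic", behavior_mode = spec$behavior_mode,
        behavior_profile = spec$behavior_profile,
        sample_rate = fs, duration = spec$duration,
        channel_roles = stats::setNames(ch$role, ch$label),
        track_length = spec$track_length,
        goal_zone_width = spec$goal_zone_width,
        goal_zone_offset = spec$goal_zone_offset,
        seed = spec$seed
      ),
      ground_truth = list(
        mixing = cvec, reference = ref,
        theta_band = spec$theta_band,
        coherence_targets = spec$coherence_targets,
        artifact_intervals = artifact_iv,
        theta_phase = theta_phase,
        units = spec$units
      )
    ),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %d signal(s), %s tracking, %d spike unit(s)\n",
              length(x$signals),
              if (is.null(x$tracking)) "no" else "with",
              length(x$spikes)))
  invisible(x)
}
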