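test_that("coherent-pair mixing hits degenerate targets exactly", {
  p1 <- generate_coherent_pair(40000, 1000, 1, seed = 1)
  cs <- coherence_spectrum(p1$x, p1$y, window = 1, step = 1)
  expect_gt(min(cs$coherence), 0.999)
  p0 <- generate_coherent_pair(120000, 1000, 0, seed = 2)
  cs0 <- coherence_spectrum(p0$x, p0$y, window = 1, step = 1)
  expect_lt(mean(cs0$coherence), coherence_bias_floor(120 * 4) + 0.03)
  expect_error(generate_coherent_pair(1000, 1000, 1.2), "\\[0, 1\\]")
  # unit variance preserved by the mixing construction
  expect_equal(stats::sd(p1$y$values), 1, tolerance = 0.01)
  expect_equal(stats::sd(p0$y$values), 1, tolerance = 0.01)
})

test_that("coherent-pair estimates recover intermediate targets", {
  # the construction is frequency-flat, so the broadband mean is the
  # well-powered check at this problem size; the narrow theta band alone
  # carries ~0.03 Monte-Carlo error with 160 windows and is verified at
  # larger n in the acceptance suite
  for (tg in c(0.2, 0.5, 0.8)) {
    p <- generate_coherent_pair(160000, 1000, tg, seed = 100 + tg * 10)
    cs <- coherence_spectrum(p$x, p$y, window = 1, step = 1)
    broad <- cs$freq_hz >= 1 & cs$freq_hz <= 300
    expect_lt(abs(mean(cs$coherence[broad]) - tg), 0.03)
    sel <- cs$freq_hz >= 6 & cs$freq_hz <= 12
    expect_lt(abs(mean(cs$coherence[sel]) - tg), 0.08)
  }
})

test_that("phase-locked spikes reproduce von Mises statistics", {
  fs <- 1000; dur <- 600
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  phase <- signal_trace((2 * pi * 8 * t) %% (2 * pi) - pi, fs)
  # kappa = 0: uniform phases, tiny resultant
  sp0 <- generate_phase_locked_spikes(phase, base_rate = 10, kappa = 0,
                                      seed = 3)
  idx <- pmin(round(sp0$time_s * fs) + 1, length(t))
  r0 <- Mod(mean(exp(1i * phase$values[idx])))
  expect_lt(r0, 0.05)
  # kappa = 5: resultant matches I1/I0
  sp5 <- generate_phase_locked_spikes(phase, base_rate = 10, kappa = 5,
                                      mu = 1, seed = 4)
  idx5 <- pmin(round(sp5$time_s * fs) + 1, length(t))
  r5 <- Mod(mean(exp(1i * phase$values[idx5])))
  expect_equal(r5, besselI(5, 1) / besselI(5, 0), tolerance = 0.05)
  # kappa = 2 at 231 degrees: circular mean recovered within 10 degrees
  mu <- 231 * pi / 180
  sp2 <- generate_phase_locked_spikes(phase, base_rate = 5, kappa = 2,
                                      mu = mu, seed = 5)
  idx2 <- pmin(round(sp2$time_s * fs) + 1, length(t))
  ang <- (Arg(mean(exp(1i * phase$values[idx2]))) * 180 / pi) %% 360
  expect_lt(min(abs(ang - 231), 360 - abs(ang - 231)), 10)
  expect_error(generate_phase_locked_spikes(phase, base_rate = -1), "positive")
})

test_that("spike counts scale linearly with base rate", {
  fs <- 1000
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  phase <- signal_trace((2 * pi * 8 * t) %% (2 * pi) - pi, fs)
  n5 <- nrow(generate_phase_locked_spikes(phase, 5, kappa = 2, seed = 6))
  n20 <- nrow(generate_phase_locked_spikes(phase, 20, kappa = 2, seed = 7))
  expect_equal(n20 / n5, 4, tolerance = 0.05 * 4)
  expect_equal(n5 / 300, 5, tolerance = 0.25)
})

test_that("behaviour generators respect their contracts", {
  spec_hc <- session_spec(duration = 200, behavior_mode = "homecage",
                          seed = 8)
  hc <- generate_behavior(spec_hc)
  expect_equal(nrow(hc$events), 0)
  sp <- compute_speed(hc$tracking)
  expect_gt(mean(sp$values > 3), 0.1)   # speed distribution straddles 3 cm/s
  expect_lt(mean(sp$values > 3), 0.9)
  spec_gd <- session_spec(duration = 200, behavior_mode = "linear_track",
                          behavior_profile = "goal_directed", seed = 9)
  gd <- generate_behavior(spec_gd)
  # rewards coincide with goal-zone positions
  x_at <- stats::approx(gd$tracking$time_s, gd$tracking$x_cm,
                        xout = gd$events$time_s)$y
  in_zone <- (x_at >= 10 & x_at <= 15) | (x_at >= 85 & x_at <= 90)
  expect_true(all(in_zone))
  expect_true(all(gd$tracking$x_cm >= 0 & gd$tracking$x_cm <= 100))
})

test_that("goal-directed sessions out-reward exploratory ones", {
  n_rewards <- function(profile, seed) {
    spec <- session_spec(duration = 120, behavior_mode = "linear_track",
                         behavior_profile = profile, seed = seed)
    nrow(generate_behavior(spec)$events)
  }
  wins <- vapply(1:20, function(s) {
    n_rewards("goal_directed", s) > n_rewards("exploratory", s)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("session generation honours coherence targets and rejects impossible ones", {
  spec <- three_channel_spec(targets = c(crusI = 0.5, lobII_III = 0.46),
                             duration = 240, seed = 10,
                             line_noise_amplitude = 0)
  b <- generate_session(spec)
  cs_c <- coherence_spectrum(b$signals$hpc_left, b$signals$crusI,
                             window = 1, step = 1)
  cs_l <- coherence_spectrum(b$signals$hpc_left, b$signals$lobII_III,
                             window = 1, step = 1)
  # interior theta bins: band-edge bins take leakage dilution from the
  # incoherent out-of-band content (taper bandwidth 2.5 Hz)
  sel <- cs_c$freq_hz >= 8 & cs_c$freq_hz <= 10
  expect_lt(abs(mean(cs_c$coherence[sel]) - 0.5), 0.05)
  expect_lt(abs(mean(cs_l$coherence[sel]) - 0.46), 0.05)
  expect_gt(mean(cs_c$coherence[sel]), mean(cs_l$coherence[sel]))
  # out-of-band coherence sits at the estimator floor
  out <- cs_c$freq_hz >= 20 & cs_c$freq_hz <= 40
  expect_lt(mean(cs_c$coherence[out]), coherence_bias_floor(236 * 4) + 0.03)
  # channel variance is unit before line noise / artifacts
  expect_equal(stats::sd(b$signals$crusI$values), 1, tolerance = 0.01)
  # a cerebellar-cerebellar target inconsistent with the product rule fails
  bad <- session_spec(
    channels = spec$channels,
    coherence_targets = tibble::tibble(
      chan_a = c("hpc_left", "hpc_left", "crusI"),
      chan_b = c("crusI", "lobII_III", "lobII_III"),
      target = c(0.5, 0.46, 0.9)),
    duration = 60, seed = 1)
  expect_error(generate_session(bad), "not realizable")
})

test_that("session generation is reproducible for a fixed seed", {
  spec <- three_channel_spec(duration = 60, seed = 77,
                             behavior_mode = "linear_track")
  b1 <- generate_session(spec)
  b2 <- generate_session(spec)
  expect_identical(b1$signals$hpc_left$values, b2$signals$hpc_left$values)
  expect_identical(b1$tracking$x_cm, b2$tracking$x_cm)
  expect_identical(b1$events$reward$time_s, b2$events$reward$time_s)
})

test_that("50 Hz line noise appears at the requested amplitude", {
  spec <- three_channel_spec(duration = 60, seed = 13,
                             line_noise_amplitude = 0.5)
  b <- generate_session(spec)
  sg <- multitaper_spectrogram(b$signals$crusI, step = 1)
  ms <- colMeans(sg$values)
  # a 0.5-amplitude sinusoid carries power 0.125 concentrated at 50 Hz
  expect_gt(ms[sg$freqs == 50], 5 * ms[sg$freqs == 45])
})
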