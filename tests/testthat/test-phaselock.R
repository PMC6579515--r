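test_that("theta phase of a pure tone follows the analytic convention", {
  fs <- 1000
  dur <- 20
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  lfp <- signal_trace(cos(2 * pi * 8 * t), fs)
  ph <- instantaneous_theta_phase(lfp)
  core <- 2000:18000
  # phase is zero at each cosine maximum
  maxima <- which(abs((t * 8) %% 1) < 1e-9)
  maxima <- maxima[maxima %in% core]
  expect_lt(max(abs(ph$values[maxima])) * 180 / pi, 2)
  # unwrapped phase advances at 2*pi*8 per second
  dphi <- diff(ph$values[core])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  expect_equal(mean(dphi), 2 * pi * 8 / fs, tolerance = 1e-4)
  expect_error(instantaneous_theta_phase(lfp, band = c(12, 6)), "f_lo < f_hi")
  # amplitude scaling leaves phases untouched
  # amplitude invariance up to IIR floating-point noise (~1e-4 rad)
  lfp2 <- signal_trace(57 * lfp$values, fs)
  ph2 <- instantaneous_theta_phase(lfp2)
  expect_lt(max(abs(ph2$values[core] - ph$values[core])), 1e-3)
})

test_that("resultant length behaves at the extremes", {
  fs <- 1000
  phase <- signal_trace(rep(pi / 2, 5000), fs)
  spikes <- spike_train("u", seq(0.1, 4.9, by = 0.1))
  r <- phase_locking_stats(spikes, phase)
  expect_equal(r$resultant_length, 1)
  expect_equal(r$mean_angle_deg, 90)
  expect_lt(r$rayleigh_p, 1e-6)
  expect_true(r$significant)
  # antipodal pair of equal masses: resultant zero
  ph2 <- signal_trace(c(rep(0, 2500), rep(pi, 2500)), fs)
  spikes2 <- spike_train("u", c(seq(0.1, 2.4, by = 0.1),
                                seq(2.6, 4.9, by = 0.1)))
  r2 <- phase_locking_stats(spikes2, ph2)
  expect_lt(r2$resultant_length, 1e-10)
})

test_that("Rayleigh approximation matches a Monte-Carlo uniform null", {
  # null distribution of R for small n, simulated directly
  set.seed(36)
  n <- 12
  r_null <- replicate(200000, Mod(mean(exp(1i * stats::runif(n, -pi, pi)))))
  for (r_obs in c(0.25, 0.4, 0.55)) {
    p_mc <- mean(r_null >= r_obs)
    expect_equal(rayleigh_p(n, r_obs), p_mc, tolerance = 0.01)
  }
})

test_that("insufficient spikes yield a flagged result, not an error", {
  fs <- 1000
  phase <- signal_trace(stats::runif(5000, -pi, pi), fs)
  few <- spike_train("u", c(0.5, 1.5, 2.5))
  r <- phase_locking_stats(few, phase)
  expect_true(r$insufficient_data)
  expect_false(r$significant)
  expect_true(is.na(r$rayleigh_p))
})

test_that("von Mises units are detected with correct angles at n = 200", {
  fs <- 1000; dur <- 400
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  phase <- signal_trace((2 * pi * 8 * t + pi) %% (2 * pi) - pi, fs)
  hits <- vapply(1:40, function(s) {
    sp <- generate_phase_locked_spikes(phase, base_rate = 0.55, kappa = 2,
                                       mu = 231 * pi / 180, seed = s)
    if (nrow(sp) > 200) sp <- sp[1:200, ]
    r <- phase_locking_stats(sp, phase)
    err <- abs(r$mean_angle_deg - 231)
    c(r$significant, min(err, 360 - err) <= 10)
  }, numeric(2))
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.95)
})

test_that("photo-identification classifies a rate-tripling unit", {
  onsets <- seq(5, 103, by = 2)
  set.seed(37)
  base <- sort(stats::runif(stats::rpois(1, 20 * 110), 0, 110))
  extra <- unlist(lapply(onsets, function(t0) {
    t0 + stats::runif(stats::rpois(1, 40 * 0.1), 0, 0.1)
  }))
  unit <- spike_train("u", sort(c(base, extra)))
  r <- classify_photoresponse(unit, onsets)
  expect_true(r$classified)
  expect_equal(r$direction, "increase")
  expect_gt(r$statistic, 1.96)
  # suppressed unit: decrease
  set.seed(38)
  sup_times <- sort(stats::runif(stats::rpois(1, 30 * 110), 0, 110))
  in_light <- vapply(sup_times, function(ts) {
    any(ts >= onsets & ts < onsets + 0.1)
  }, logical(1))
  sup <- spike_train("u", sup_times[!in_light])
  rs <- classify_photoresponse(sup, onsets)
  expect_true(rs$classified)
  expect_equal(rs$direction, "decrease")
})

test_that("photo-identification flags silent and spikeless units", {
  onsets <- seq(5, 103, by = 2)
  r <- classify_photoresponse(numeric(0), onsets)
  expect_true(r$unclassifiable)
  expect_false(r$classified)
  expect_error(classify_photoresponse(numeric(0), 1:5), "10 light trials")
})
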