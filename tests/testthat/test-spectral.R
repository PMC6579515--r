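test_that("DPSS tapers are orthonormal and well concentrated", {
  v <- dpss_tapers(1000, nw = 2.5, k = 4)
  g <- crossprod(v)
  expect_equal(g, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  # leading taper concentrates its energy inside the design bandwidth
  f <- stats::fft(c(v[, 1], rep(0, 9000)))
  p <- Mod(f)^2
  inband <- sum(p[1:26]) + sum(p[(10000 - 24):10000])  # |f| <= 2.5/N
  expect_gt(inband / sum(p), 0.999)
})

test_that("spectrogram is flat for white noise and integrates to variance", {
  tr <- white_trace(120000, seed = 5)
  sg <- multitaper_spectrogram(tr, window = 1, step = 1)
  ms <- colMeans(sg$values)
  sel <- sg$freqs >= 1 & sg$freqs <= 300
  # flat to 10% after averaging away single-bin estimator noise (10 Hz
  # chunks; single bins at 480 dof still carry ~6% noise)
  chunks <- tapply(ms[sel], (sg$freqs[sel] - 1) %/% 10, mean)
  expect_lt(max(abs(chunks / mean(chunks) - 1)), 0.10)
  # Parseval: per-window integral of the density ~ windowed variance
  df <- sg$freqs[2] - sg$freqs[1]
  totals <- rowSums(sg$values) * df
  wins <- matrix(tr$values[1:(120 * 1000)], nrow = 1000)
  vars <- apply(wins, 2, function(w) mean(w^2))
  expect_equal(mean(totals / vars), 1, tolerance = 0.1)
})

test_that("an 8 Hz tone produces a sharp, strong spectral peak", {
  sg <- multitaper_spectrogram(sine_trace(8, dur = 30), window = 1, step = 1)
  ms <- colMeans(sg$values)
  peak_bin <- which.max(ms)
  expect_equal(sg$freqs[peak_bin], 8)
  expect_gt(10 * log10(ms[sg$freqs == 8] / ms[sg$freqs == 20]), 20)
})

test_that("self-coherence is one and coherence ignores amplitude scaling", {
  tr <- white_trace(20000, seed = 9)
  cg <- multitaper_coherogram(tr, tr, window = 1, step = 1)
  expect_equal(max(abs(cg$values - 1)), 0, tolerance = 1e-9)
  other <- white_trace(20000, seed = 10)
  cs1 <- coherence_spectrum(tr, other, window = 1, step = 1)
  scaled <- signal_trace(other$values * 37.5, other$sample_rate)
  cs2 <- coherence_spectrum(tr, scaled, window = 1, step = 1)
  expect_equal(cs1$coherence, cs2$coherence, tolerance = 1e-10)
})

test_that("zero-lag mixtures show magnitude but no imaginary coherency", {
  set.seed(12)
  n <- 300000; fs <- 1000
  shared <- sine_trace(8, dur = n / fs, amp = 2)$values + stats::rnorm(n)
  x <- signal_trace(shared + 0.5 * stats::rnorm(n), fs)
  y <- signal_trace(shared + 0.5 * stats::rnorm(n), fs)
  cs <- coherence_spectrum(x, y, window = 1, step = 1)
  at8 <- cs$freq_hz == 8
  expect_gt(cs$coherence[at8], 0.7)
  expect_lt(abs(cs$imaginary[at8]), 0.05)
  sel <- cs$freq_hz >= 1 & cs$freq_hz <= 300
  expect_lt(max(abs(cs$imaginary[sel])), 0.05)
})

test_that("pooled coherence bias shrinks with window x taper dof", {
  x <- white_trace(240000, seed = 14)
  y <- white_trace(240000, seed = 15)
  cs1 <- coherence_spectrum(x, y, window = 1, step = 1)   # 240 windows
  cs2 <- coherence_spectrum(x, y, window = 2, step = 2)   # 120 windows
  expect_lt(mean(cs1$coherence), mean(cs2$coherence))
  floor1 <- coherence_bias_floor(240 * 4)
  expect_lt(abs(mean(cs1$coherence) - floor1), 0.02)
  floor2 <- coherence_bias_floor(120 * 4)
  expect_lt(abs(mean(cs2$coherence) - floor2), 0.02)
})

test_that("band series averages the right bins and tracks AM envelopes", {
  map <- tf_map(seq(0.5, 10, by = 0.1), 0:100,
                matrix(1, 96, 101), 1, 0.1, 4, kind = "coherence")
  bs <- band_series(map, c(6, 12))
  expect_true(all(bs$values == 1))
  full <- band_series(map, c(0, 100))
  expect_equal(full$values, rowMeans(map$values))
  expect_error(band_series(map, c(200, 300)), "intersect")
  # amplitude-modulated 8 Hz: theta power tracks the modulation envelope
  fs <- 1000; dur <- 60
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  env <- 1 + 0.8 * sin(2 * pi * 0.05 * t)
  am <- signal_trace(env * sin(2 * pi * 8 * t) + 0.1 * stats::rnorm(length(t)), fs)
  sg <- multitaper_spectrogram(am, window = 1, step = 0.1)
  th <- band_series(sg, c(6, 12))
  env_at <- 1 + 0.8 * sin(2 * pi * 0.05 * trace_times(th))
  expect_gt(stats::cor(th$values, env_at^2), 0.8)
})

test_that("spectral z-scoring is scale invariant and flags theta peaks", {
  sp <- tibble::tibble(freq_hz = seq(0, 500), power = rep(2, 501))
  expect_true(all(zscore_power_spectrum(sp)$z == 0))
  set.seed(16)
  sp2 <- tibble::tibble(freq_hz = seq(0, 500),
                        power = stats::rexp(501) + 1)
  z1 <- zscore_power_spectrum(sp2)
  sp3 <- sp2; sp3$power <- sp3$power * 123.4
  expect_equal(z1$z, zscore_power_spectrum(sp3)$z, tolerance = 1e-12)
  # hippocampus-like synthetic: theta z beats 30 Hz z
  spec <- three_channel_spec(duration = 120, seed = 17)
  b <- generate_session(spec)
  sg <- multitaper_spectrogram(preprocess_lfp(b$signals$hpc_left),
                               step = 1)
  z <- zscore_power_spectrum(mean_spectrum(sg))
  expect_gt(z$z[z$freq_hz == 8], z$z[z$freq_hz == 30])
})

test_that("line-band masking is surgical and idempotent", {
  map <- tf_map(seq(0.5, 5, by = 0.1), 0:100,
                matrix(stats::runif(46 * 101), 46, 101), 1, 0.1, 4,
                kind = "coherence")
  m1 <- mask_line_band(map)
  expect_true(all(is.na(m1$values[, m1$freqs > 48 & m1$freqs < 52])))
  keep <- m1$freqs <= 48 | m1$freqs >= 52
  expect_equal(m1$values[, keep], map$values[, keep])
  m2 <- mask_line_band(m1)
  expect_equal(m2$values, m1$values)
  # low-gamma band averaging (30-48) untouched by the mask
  bs_before <- band_series(map, c(30, 48))
  bs_after <- band_series(m1, c(30, 48))
  expect_equal(bs_after$values, bs_before$values)
  # band fully outside the axis: identity
  m3 <- mask_line_band(map, band = c(300, 310))
  expect_equal(m3$values, map$values)
})

test_that("profile pooling is an occupancy-weighted mean", {
  prof <- distance_profile(seq(-99.5, -0.5, by = 1), rep(0.7, 100),
                           rep(1, 100))
  expect_equal(pool_profile(prof, c(-60, -20)), 0.7)
  one <- pool_profile(prof, c(-50.9, -50.1))   # isolates the -50.5 bin
  expect_equal(one, 0.7)
  set.seed(18)
  prof2 <- distance_profile(seq(-99.5, -0.5, by = 1), stats::runif(100),
                            stats::rexp(100))
  sel <- prof2$bin_center_cm >= -60 & prof2$bin_center_cm <= -20
  oracle <- sum(prof2$value[sel] * prof2$occupancy_s[sel]) /
    sum(prof2$occupancy_s[sel])
  expect_equal(pool_profile(prof2, c(-60, -20)), oracle)
  empty <- distance_profile(-50, NA_real_, 0)
  expect_warning(out <- pool_profile(empty, c(-60, -20)), "occupied")
  expect_true(is.na(out))
})

test_that("hemisphere averaging passes through missing inputs", {
  expect_equal(average_hemispheres(0.4, 0.6), 0.5)
  expect_equal(average_hemispheres(0.4, NULL), 0.4)
  expect_equal(average_hemispheres(NULL, 0.6), 0.6)
  expect_true(is.na(average_hemispheres(NULL, NULL)))
  a <- tibble::tibble(freq_hz = 1:3, coherence = c(0.2, 0.4, 0.6))
  b <- tibble::tibble(freq_hz = 1:3, coherence = c(0.4, 0.6, 0.8))
  expect_equal(average_hemispheres(a, b)$coherence, c(0.3, 0.5, 0.7))
  expect_equal(average_hemispheres(a, b)$freq_hz, 1:3)
})

test_that("excluded windows drop without disturbing retained ones", {
  tr <- white_trace(30000, seed = 19)
  excl <- interval_set(10, 12)
  sg_all <- multitaper_spectrogram(tr, step = 0.5)
  sg_masked <- multitaper_spectrogram(tr, step = 0.5, exclude = excl)
  # a window [c - 0.5, c + 0.5) overlaps [10, 12) iff 9.5 < c < 12.5
  overlap <- sg_masked$window_centers > 9.5 + 1e-9 &
    sg_masked$window_centers < 12.5 - 1e-9
  expect_true(all(is.na(sg_masked$values[overlap, ])))
  expect_equal(sg_masked$values[!overlap, ], sg_all$values[!overlap, ])
})
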