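test_that("speed computation handles stationary and uniform motion", {
  tt <- seq(0, 60, by = 1 / 30)
  still <- tracking_trace(tt, rep(10, length(tt)), rep(5, length(tt)))
  sp <- compute_speed(still)
  expect_true(all(sp$values == 0))
  unif <- tracking_trace(tt, 5 * tt, rep(0, length(tt)))
  spu <- compute_speed(unif)
  core <- spu$values[5:(length(spu$values) - 5)]
  expect_true(all(abs(core - 5) < 0.1))
  expect_error(compute_speed(tracking_trace(0, 0, 0)), "2 tracking samples")
})

test_that("speed agrees with a brute-force central difference oracle", {
  set.seed(23)
  tt <- seq(0, 120, by = 1 / 30)
  x <- cumsum(stats::rnorm(length(tt), 0, 0.3))
  y <- cumsum(stats::rnorm(length(tt), 0, 0.3))
  tr <- tracking_trace(tt, x, y)
  sp <- compute_speed(tr, smooth_s = 0)
  # oracle: central differences on raw positions, block means per 0.1 s
  n <- length(tt)
  vx <- (x[3:n] - x[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  vy <- (y[3:n] - y[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  v <- c(NA, sqrt(vx^2 + vy^2), NA); v[1] <- v[2]; v[n] <- v[n - 1]
  agg <- tapply(v, floor(tt * 10), mean, na.rm = TRUE)
  centers <- (as.numeric(names(agg)) + 0.5) / 10
  keep <- centers %in% trace_times(sp)
  got <- sp$values[match(centers[keep], trace_times(sp))]
  expect_equal(got, unname(as.numeric(agg))[keep], tolerance = 1e-6)
})

test_that("active-epoch detection matches an exhaustive per-sample scan", {
  fs <- 10
  # constant suprathreshold speed: one interval spanning the trace
  const <- signal_trace(rep(5, 7200), fs, t0 = 0.05)
  ep <- detect_active_epochs(const)
  expect_equal(nrow(ep), 1)
  expect_equal(interval_total(ep), 720)
  # 3.9 s above threshold amid zeros: below the 4 s minimum
  v <- c(rep(0, 50), rep(5, 39), rep(0, 50))
  expect_equal(nrow(detect_active_epochs(signal_trace(v, fs))), 0)
  v4 <- c(rep(0, 50), rep(5, 40), rep(0, 50))
  expect_equal(nrow(detect_active_epochs(signal_trace(v4, fs))), 1)
  # randomized traces: exact equality with the oracle
  set.seed(24)
  for (rep in 1:100) {
    vals <- stats::rexp(sample(50:400, 1), rate = 1 / 3)
    sp <- signal_trace(vals, fs, t0 = round(stats::runif(1), 1))
    got <- detect_active_epochs(sp, threshold = 3, min_duration = 4)
    want <- brute_force_epochs(vals, fs, sp$t0, 3, 4)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("epoch detection is monotone in the threshold", {
  set.seed(25)
  vals <- stats::rexp(2000, 1 / 3)
  sp <- signal_trace(vals, 10)
  hi <- detect_active_epochs(sp, threshold = 4)
  lo <- detect_active_epochs(sp, threshold = 2)
  grid <- seq(0, 200, by = 0.05)
  cover_hi <- interval_contains(hi, grid)
  cover_lo <- interval_contains(lo, grid)
  expect_true(all(cover_lo[cover_hi]))
})

test_that("run segmentation counts traversals and flags turnarounds", {
  spec <- session_spec(duration = 300, behavior_mode = "linear_track",
                       behavior_profile = "goal_directed", seed = 26)
  beh <- generate_behavior(spec)
  runs <- segment_runs(beh$tracking, beh$events)
  expect_equal(nrow(runs), nrow(beh$events) - 1)
  expect_true(all(runs$direction %in% c(-1L, 1L)))
  # distance at the reward sample is within (-1, 0]
  d <- distance_to_reward(runs$reward_time_s - 1e-3, beh$tracking, runs)
  expect_true(all(d > -1 & d <= 0))
  # exploratory sessions contain flagged non-monotonic runs, still retained
  spec_ex <- session_spec(duration = 600, behavior_mode = "linear_track",
                          behavior_profile = "exploratory", seed = 27)
  beh_ex <- generate_behavior(spec_ex)
  runs_ex <- segment_runs(beh_ex$tracking, beh_ex$events)
  expect_gt(nrow(runs_ex), 0)
  expect_true(any(runs_ex$non_monotonic))
  expect_equal(nrow(segment_runs(beh$tracking, numeric(0))), 0)
})

test_that("distance binning conserves occupancy and normalises correctly", {
  spec <- session_spec(duration = 300, behavior_mode = "linear_track",
                       behavior_profile = "goal_directed", seed = 28)
  beh <- generate_behavior(spec)
  runs <- segment_runs(beh$tracking, beh$events)
  grid_t0 <- 0.05
  ones <- signal_trace(rep(1, 3005), 10, t0 = grid_t0)  # covers every run
  prof <- bin_by_distance(ones, beh$tracking, runs)
  occupied <- prof$occupancy_s > 0
  expect_true(all(prof$value[occupied] == 1))
  expect_true(all(is.na(prof$value[!occupied])))
  run_span <- max(runs$end_s) - min(runs$start_s)
  expect_equal(sum(prof$occupancy_s), run_span, tolerance = 0.1 + 1e-9)
  # random series: per-bin means equal a brute-force groupby
  set.seed(29)
  vals <- stats::rnorm(3005)
  ser <- signal_trace(vals, 10, t0 = grid_t0)
  prof2 <- bin_by_distance(ser, beh$tracking, runs)
  d <- distance_to_reward(trace_times(ser), beh$tracking, runs)
  keep <- !is.na(d)
  bin <- findInterval(d[keep], seq(-100, 0, by = 1), rightmost.closed = TRUE)
  oracle <- tapply(vals[keep], bin, mean)
  got <- prof2$value[as.integer(names(oracle))]
  expect_equal(got, unname(as.numeric(oracle)))
})

test_that("binning is independent of run order", {
  spec <- session_spec(duration = 200, behavior_mode = "linear_track",
                       seed = 30)
  beh <- generate_behavior(spec)
  runs <- segment_runs(beh$tracking, beh$events)
  ser <- signal_trace(stats::rnorm(1995), 10, t0 = 0.05)
  p1 <- bin_by_distance(ser, beh$tracking, runs)
  p2 <- bin_by_distance(ser, beh$tracking, runs[sample(nrow(runs)), ])
  expect_equal(p1$value, p2$value)
  expect_equal(p1$occupancy_s, p2$occupancy_s)
})
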