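#' Instantaneous speed from position tracking
#'
#' Positions are smoothed with a 0.5 s moving average (tracker jitter at
#' 30 Hz otherwise inflates finite-difference speed), differentiated by
#' central differences at the tracking rate, and block-resampled onto the
#' analysis grid (10 Hz by default, matching the spectrogram window-centre
#' grid).
#'
#' @param tracking A [tracking_trace()] (>= 2 samples).
#' @param out_rate Output rate (Hz), default 10.
#' @param smooth_s Position-smoothing window (s), default 0.5.
#' @return A [signal_trace()] of nonnegative speed (cm/s) at `out_rate`.
#' @export
compute_speed <- function(tracking, out_rate = 10, smooth_s = 0.5) {
  stopifnot(inherits(tracking, "tracking_trace") || is.data.frame(tracking))
  if (nrow(tracking) < 2) stop("need >= 2 tracking samples", call. = FALSE)
  tt <- tracking$time_s
  fr <- 1 / stats::median(diff(tt))
  w <- max(1L, round(smooth_s * fr))
  sm <- function(v) as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  xs <- sm(tracking$x_cm); ys <- sm(tracking$y_cm)
  # fill smoothing edges with nearest valid value
  fill <- function(v) {
    ok <- which(!is.na(v))
    v[seq_len(ok[1] - 1)] <- v[ok[1]]
    v[seq(ok[length(ok)] + 1, length.out = length(v) - ok[length(ok)])] <- v[ok[length(ok)]]
    v
  }
  xs <- fill(xs); ys <- fill(ys)
  n <- length(tt)
  vx <- c(NA, (xs[3:n] - xs[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)]), NA)
  vy <- c(NA, (ys[3:n] - ys[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)]), NA)
  sp <- sqrt(vx^2 + vy^2)
  sp[1] <- sp[2]; sp[n] <- sp[n - 1]
  # block average onto the out_rate grid; bin centres at (k + 1/2)/out_rate
  bins <- floor(tt * out_rate)
  agg <- tapply(sp, bins, mean, na.rm = TRUE)
  centers <- (as.numeric(names(agg)) + 0.5) / out_rate
  grid <- seq(min(centers), max(centers), by = 1 / out_rate)
  vals <- stats::approx(centers, as.numeric(agg), xout = grid, rule = 2)$y
  signal_trace(pmax(vals, 0), sample_rate = out_rate, t0 = grid[1],
               label = "speed", units = "cm/s")
}

#' Detect sustained active-movement epochs
#'
#' Maximal intervals during which the speed exceeds `threshold` at every
#' sample and whose duration is at least `min_duration` (the "sustained
#' speed above 3 cm/s for a minimum of 4 s" inclusion rule). `dip_tolerance`
#' optionally allows that many consecutive sub-threshold samples inside an
#' epoch (default 0: strict).
#'
#' @param speed A [signal_trace()] of speed at the analysis rate.
#' @param threshold Speed threshold (cm/s), default 3.
#' @param min_duration Minimum epoch length (s), default 4.
#' @param dip_tolerance Maximum run of sub-threshold samples tolerated inside
#'   an epoch, default 0.
#' @return An [interval_set()] of active epochs (sample-extent based,
#'   half-open).
#' @export
detect_active_epochs <- function(speed, threshold = 3, min_duration = 4,
                                 dip_tolerance = 0) {
  stopifnot(inherits(speed, "signal_trace"))
  fs <- speed$sample_rate
  above <- speed$values > threshold
  above[is.na(above)] <- FALSE
  if (dip_tolerance > 0) {
    r <- rle(above)
    short_dip <- !r$values & r$lengths <= dip_tolerance
    # dips only bridge when flanked by supra-threshold runs
    idx <- which(short_dip)
    idx <- idx[idx > 1 & idx < length(r$values)]
    r$values[idx] <- TRUE
    above <- inverse.rle(r)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs) >= min_duration
  if (!any(keep)) return(interval_set())
  s_t <- speed$t0 + (starts[keep] - 1) / fs
  e_t <- speed$t0 + ends[keep] / fs
  interval_set(s_t, e_t)
}

#' Segment a linear-track session into runs
#'
#' One run per inter-reward traversal: run i spans from reward i to reward
#' i+1, with direction given by net displacement and the distance-to-reward
#' convention "negative approaching reward, 0 at reward". Runs containing a
#' mid-track turnaround (along-track position reversing by more than
#' `turn_tol` cm) are flagged `non_monotonic` but retained, so exploratory
#' sessions remain analysable.
#'
#' @param tracking A [tracking_trace()] on a linear track (x = along-track
#'   cm).
#' @param rewards Tibble of reward times (`time_s`) or numeric vector.
#' @param track_length Track length (cm).
#' @param goal_offset Offset of goal zones from the track ends (cm); used
#'   only for bookkeeping in the output.
#' @param turn_tol Reversal tolerance (cm), default 2.
#' @return A tibble (`run_table`) with one row per run: `run`, `start_s`,
#'   `end_s`, `direction`, `reward_time_s`, `reward_x_cm`, `non_monotonic`.
#'   Empty when fewer than 2 rewards.
#' @export
segment_runs <- function(tracking, rewards, track_length = 100,
                         goal_offset = 10, turn_tol = 2) {
  rt <- if (is.data.frame(rewards)) rewards$time_s else as.numeric(rewards)
  empty <- tibble::tibble(run = integer(0), start_s = numeric(0),
                          end_s = numeric(0), direction = integer(0),
                          reward_time_s = numeric(0), reward_x_cm = numeric(0),
                          non_monotonic = logical(0))
  if (length(rt) < 2) return(empty)
  rt <- sort(rt)
  out <- vector("list", length(rt) - 1)
  for (i in seq_len(length(rt) - 1)) {
    sel <- tracking$time_s >= rt[i] & tracking$time_s <= rt[i + 1]
    xs <- tracking$x_cm[sel]
    if (length(xs) < 2) next
    dir <- sign(xs[length(xs)] - xs[1])
    if (dir == 0) dir <- 1
    along <- dir * xs
    non_mono <- (max(cummax(along) - along)) > turn_tol
    reward_x <- stats::approx(tracking$time_s, tracking$x_cm,
                              xout = rt[i + 1], rule = 2)$y
    out[[i]] <- tibble::tibble(
      run = i, start_s = rt[i], end_s = rt[i + 1], direction = as.integer(dir),
      reward_time_s = rt[i + 1], reward_x_cm = reward_x,
      non_monotonic = non_mono)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Signed distance to the upcoming reward
#'
#' For times inside a run, returns `-(along-track distance remaining to the
#' rewarded goal position)`: negative on approach, 0 at the reward, clamped
#' to `[-track_length, 0]`. Times outside every run give `NA`.
#'
#' @param times Numeric query times (s).
#' @param tracking A [tracking_trace()].
#' @param runs A run table from [segment_runs()].
#' @param track_length Track length (cm).
#' @return Numeric vector of signed distances (cm).
#' @export
distance_to_reward <- function(times, tracking, runs, track_length = 100) {
  out <- rep(NA_real_, length(times))
  if (nrow(runs) == 0) return(out)
  x_at <- stats::approx(tracking$time_s, tracking$x_cm, xout = times,
                        rule = 2)$y
  for (i in seq_len(nrow(runs))) {
    sel <- times >= runs$start_s[i] & times < runs$end_s[i]
    if (!any(sel)) next
    d <- -abs(runs$reward_x_cm[i] - x_at[sel])
    out[sel] <- pmax(d, -track_length)
  }
  out
}

#' Distance profile container
#'
#' @param bin_center_cm Bin centres (cm; negative = before reward).
#' @param value Per-bin (optionally per-frequency) values.
#' @param occupancy_s Time spent in each bin (s).
#' @param freq_hz Optional frequency column for frequency-resolved profiles.
#' @return Tibble of class `distance_profile`.
#' @export
distance_profile <- function(bin_center_cm, value, occupancy_s,
                             freq_hz = NULL) {
  out <- tibble::tibble(bin_center_cm = bin_center_cm, value = value,
                        occupancy_s = occupancy_s)
  if (!is.null(freq_hz)) out$freq_hz <- freq_hz
  class(out) <- c("distance_profile", class(out))
  out
}

#' Occupancy-normalised distance binning
#'
#' Averages a series (speed, band power, band coherence — anything on the
#' 10 Hz analysis grid) by distance from the upcoming reward in 1 cm bins,
#' time-weighting by sample duration so the per-bin mean is
#' occupancy-normalised. Per-bin occupancy (s) is returned; unoccupied bins
#' are marked missing (`NA` value, 0 occupancy).
#'
#' @param series A [signal_trace()] on the analysis grid (may contain `NA`
#'   at excluded windows; those samples contribute neither value nor
#'   occupancy).
#' @param tracking A [tracking_trace()].
#' @param runs A run table from [segment_runs()].
#' @param track_length Track length (cm).
#' @param bin_width Bin width (cm), default 1.
#' @return A [distance_profile()] covering `[-track_length, 0)`.
#' @export
bin_by_distance <- function(series, tracking, runs, track_length = 100,
                            bin_width = 1) {
  stopifnot(inherits(series, "signal_trace"))
  dt <- 1 / series$sample_rate
  times <- trace_times(series)
  d <- distance_to_reward(times, tracking, runs, track_length)
  edges <- seq(-track_length, 0, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  keep <- !is.na(d) & !is.na(series$values)
  bin <- findInterval(d[keep], edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L
  bin[bin > length(centers)] <- length(centers)
  v <- series$values[keep]
  num <- tapply(v, bin, sum)
  cnt <- tapply(v, bin, length)
  value <- rep(NA_real_, length(centers))
  occ <- rep(0, length(centers))
  idx <- as.integer(names(num))
  value[idx] <- as.numeric(num) / as.numeric(cnt)
  occ[idx] <- as.numeric(cnt) * dt
  distance_profile(centers, value, occ)
}
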