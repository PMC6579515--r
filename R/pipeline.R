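#' Analysis configuration
#'
#' Bundles every tunable parameter of the two study-shaped analyses, with
#' the canonical defaults: 1 s / 0.1 s / 4-taper multitaper windows, theta
#' 6-12 / beta 13-29 / low-gamma 30-48 / delta 2-4 Hz bands, 3 cm/s speed
#' threshold with 4 s minimum epochs, 12-min analysis blocks, ±0.5 s
#' peri-stimulation exclusion, 1 cm distance bins pooled over (-60, -20) cm,
#' and a 1000-shuffle bootstrap at alpha 0.05. The full configuration is
#' serialised next to every result table.
#'
#' @param window,step,n_tapers Multitaper parameters (s, s, count).
#' @param bands Band table (see [band_table()]).
#' @param zscore_range Hz range for spectral z-scoring.
#' @param line_mask Hz band removed from coherence outputs.
#' @param notch_center,notch_q Notch filter parameters.
#' @param detrend_window,detrend_step Local-linear detrending windows (s).
#' @param artifact_band,artifact_z Artifact-detection band (Hz) and
#'   z-threshold.
#' @param speed_threshold_cm_s,min_epoch_s Active-movement definition.
#' @param speed_rate Analysis grid for speed (Hz).
#' @param block_min Block length (minutes) for homecage concatenation.
#' @param peristim_pad_s Peri-reward/stimulation exclusion half-width (s).
#' @param bin_cm Distance bin width (cm).
#' @param pooling_window_cm Distance window (cm) for pooled summaries.
#' @param n_shuffles,alpha Bootstrap parameters.
#' @param seed Integer seed for all stochastic steps.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(window = 1, step = 0.1, n_tapers = 4,
                            bands = band_table(),
                            zscore_range = c(0.1, 500),
                            line_mask = c(48, 52),
                            notch_center = 50, notch_q = 30,
                            detrend_window = 1, detrend_step = 0.5,
                            artifact_band = c(0.5, 5), artifact_z = 4,
                            speed_threshold_cm_s = 3, min_epoch_s = 4,
                            speed_rate = 10,
                            block_min = 12, peristim_pad_s = 0.5,
                            bin_cm = 1, pooling_window_cm = c(-60, -20),
                            n_shuffles = 1000, alpha = 0.05, seed = 1L) {
  stopifnot(all(bands$f_lo > 0), all(bands$f_lo < bands$f_hi))
  structure(
    list(window = window, step = step, n_tapers = n_tapers, bands = bands,
         zscore_range = zscore_range, line_mask = line_mask,
         notch_center = notch_center, notch_q = notch_q,
         detrend_window = detrend_window, detrend_step = detrend_step,
         artifact_band = artifact_band, artifact_z = artifact_z,
         speed_threshold_cm_s = speed_threshold_cm_s,
         min_epoch_s = min_epoch_s, speed_rate = speed_rate,
         block_min = block_min, peristim_pad_s = peristim_pad_s,
         bin_cm = bin_cm, pooling_window_cm = pooling_window_cm,
         n_shuffles = n_shuffles, alpha = alpha, seed = as.integer(seed)),
    class = "analysis_config")
}

config_params <- function(config) {
  config$bands <- as.data.frame(config$bands)
  unclass(config)
}

bundle_roles <- function(bundle) {
  roles <- unlist(bundle$metadata$channel_roles)
  if (is.null(roles)) {
    stop("bundle metadata lacks channel_roles", call. = FALSE)
  }
  roles[names(bundle$signals)]
}

hippocampal_labels <- function(roles) names(roles)[grepl("hippocampus", roles)]
cerebellar_labels <- function(roles) names(roles)[!grepl("hippocampus", roles)]

# Conditioning is staged so artifact detection can look at the signal both
# before and after local-linear detrending: slow sub-cycle transients are
# erased by the detrend stopband (which overlaps the 0.5-5 Hz artifact
# band) and are only visible before it, while weaker mid-band bursts need
# the quieter post-detrend baseline. The pipeline flags the union.
standardize_notch_bundle <- function(bundle, config) {
  lapply(bundle$signals, function(tr) {
    notch_filter(standardize(tr), center = config$notch_center,
                 quality = config$notch_q)
  })
}

detrend_bundle <- function(staged, config) {
  lapply(staged, function(tr) {
    detrend_local_linear(tr, window = config$detrend_window,
                         step = config$detrend_step)
  })
}

combined_artifacts <- function(staged, clean, config) {
  iv <- interval_set()
  for (tr in c(staged, clean)) {
    iv <- interval_union(iv, detect_artifact_intervals(
      tr, band = config$artifact_band, z_threshold = config$artifact_z,
      window = config$window, step = config$step,
      n_tapers = config$n_tapers))
  }
  iv
}

theta_band_of <- function(config) {
  b <- config$bands[config$bands$band == "theta", ]
  c(b$f_lo, b$f_hi)
}

# Pool window cross-spectra into block-mean coherence spectra, averaging the
# pooled magnitude/imaginary across blocks of `block_windows` retained
# windows.
block_coherence <- function(cs, good, block_windows) {
  idx <- which(good)
  if (length(idx) == 0) return(NULL)
  nblk <- max(1L, floor(length(idx) / block_windows))
  use <- idx[seq_len(min(length(idx), nblk * block_windows))]
  blk <- rep(seq_len(nblk), each = block_windows)[seq_along(use)]
  mags <- NULL; imags <- NULL
  for (b in seq_len(nblk)) {
    rows <- use[blk == b]
    coh <- colSums(cs$sab[rows, , drop = FALSE]) /
      sqrt(colSums(cs$saa[rows, , drop = FALSE]) *
             colSums(cs$sbb[rows, , drop = FALSE]))
    mags <- rbind(mags, Mod(coh))
    imags <- rbind(imags, Im(coh))
  }
  list(coherence = colMeans(mags), imaginary = colMeans(imags),
       n_blocks = nblk, n_windows = length(use))
}

# Per-window cross-spectral bookkeeping shared by both analyses.
pair_cross_spectra <- function(a, b, config, exclude) {
  fs <- a$sample_rate
  wlen <- round(config$window * fs)
  slen <- max(1L, round(config$step * fs))
  starts <- mt_window_starts(length(a$values), wlen, slen)
  tapers <- dpss_tapers(wlen, nw = (config$n_tapers + 1) / 2,
                        k = config$n_tapers)
  sp <- mt_window_spectra(a$values, b$values, fs = fs, wlen = wlen,
                          starts = starts, tapers = tapers)
  bad <- mt_excluded_rows(a$t0, fs, wlen, starts, exclude)
  sp$good <- !bad
  sp$centers <- a$t0 + (starts - 1 + wlen / 2) / fs
  sp$freqs <- (seq_len(ncol(sp$saa)) - 1) * fs / wlen
  sp
}

#' Home-cage analysis
#'
#' Runs the full resting/exploration workflow on one session bundle:
#' conditioning (standardize, notch, detrend), artifact and low-speed
#' exclusion (active movement = sustained speed above threshold), per-channel
#' z-scored mean power spectra, cerebello-hippocampal coherence pooled
#' within 12-min blocks of retained windows and averaged across blocks (and
#' across hemispheres where both hippocampal electrodes are present),
#' instantaneous theta power/coherence distributions with shape summaries,
#' and speed-correlation bootstrap tests.
#'
#' @param bundle A `session_bundle` with >= 1 hippocampal and >= 1
#'   cerebellar channel.
#' @param config An [analysis_config()].
#' @return A named list of tibbles (class `homecage_result`): `spectra`,
#'   `coherence`, `band_summary`, `shape`, `speed_correlation`, plus
#'   `params` and `empty` flag.
#' @export
run_homecage <- function(bundle, config = analysis_config()) {
  roles <- bundle_roles(bundle)
  hips <- hippocampal_labels(roles)
  cbs <- cerebellar_labels(roles)
  if (length(hips) < 1 || length(cbs) < 1) {
    stop("need at least one hippocampal and one cerebellar channel", call. = FALSE)
  }
  staged <- standardize_notch_bundle(bundle, config)
  clean <- detrend_bundle(staged, config)
  span <- trace_span(clean[[1]])
  artifacts <- combined_artifacts(staged, clean, config)

  active <- interval_set(span[1], span[2])
  speed <- NULL
  if (!is.null(bundle$tracking)) {
    speed <- compute_speed(bundle$tracking, out_rate = config$speed_rate)
    active <- detect_active_epochs(speed,
                                   threshold = config$speed_threshold_cm_s,
                                   min_duration = config$min_epoch_s)
  }
  analysis_mask <- interval_intersect(
    active, interval_complement(artifacts, span))
  if (interval_total(analysis_mask) < config$min_epoch_s) {
    warning("no active-movement epochs survive exclusion; returning empty result")
    return(structure(list(empty = TRUE, params = config_params(config)),
                     class = "homecage_result"))
  }
  exclude <- interval_complement(analysis_mask, span)
  theta <- theta_band_of(config)
  block_windows <- round(config$block_min * 60 / config$step)

  # per-channel spectra + instantaneous theta power
  spectra <- list(); shape_rows <- list(); cor_rows <- list()
  theta_power <- list()
  for (lab in names(clean)) {
    sg <- multitaper_spectrogram(clean[[lab]], window = config$window,
                                 step = config$step,
                                 n_tapers = config$n_tapers,
                                 exclude = exclude)
    ms <- mean_spectrum(sg)
    zs <- zscore_power_spectrum(ms, range = config$zscore_range)
    spectra[[lab]] <- dplyr::mutate(
      dplyr::left_join(ms, zs, by = "freq_hz"), channel = lab,
      .before = 1)
    bs <- band_series(sg, theta)
    vals <- bs$values[is.finite(bs$values)]
    zvals <- (vals - mean(vals)) / stats::sd(vals)
    theta_power[[lab]] <- bs
    shape_rows[[lab]] <- dplyr::mutate(distribution_shape(zvals),
                                       target = lab, kind = "theta_power",
                                       .before = 1)
    if (!is.null(speed)) {
      bt <- speed_correlation_bootstrap(bs, speed, mask = analysis_mask,
                                        n_shuffles = config$n_shuffles,
                                        alpha = config$alpha,
                                        seed = config$seed)
      cor_rows[[lab]] <- dplyr::mutate(tidy(bt), target = lab,
                                       kind = "theta_power", .before = 1)
    }
  }

  # cerebello-hippocampal coherence per region, block-pooled, hemisphere mean
  coh_rows <- list(); band_rows <- list()
  for (cb in cbs) {
    per_hemi <- list()
    per_hemi_series <- list()
    for (hp in hips) {
      cs <- pair_cross_spectra(clean[[hp]], clean[[cb]], config, exclude)
      bc <- block_coherence(cs, cs$good, block_windows)
      if (is.null(bc)) next
      per_hemi[[hp]] <- tibble::tibble(freq_hz = cs$freqs,
                                       coherence = bc$coherence,
                                       imaginary = bc$imaginary,
                                       n_blocks = bc$n_blocks)
      # instantaneous (per-window) theta coherence series
      coh_win <- cs$sab / sqrt(cs$saa * cs$sbb)
      fsel <- cs$freqs >= theta[1] & cs$freqs <= theta[2]
      ser <- rowMeans(Mod(coh_win[, fsel, drop = FALSE]))
      ser[!cs$good] <- NA_real_
      per_hemi_series[[hp]] <- new_signal_trace(
        ser, 1 / config$step, cs$centers[1],
        label = paste0(cb, "-", hp), units = "coherence")
    }
    if (length(per_hemi) == 0) next
    avg <- Reduce(average_hemispheres, per_hemi)
    avg <- mask_line_band(avg, config$line_mask)
    coh_rows[[cb]] <- dplyr::mutate(avg, region = cb, .before = 1)
    for (b in seq_len(nrow(config$bands))) {
      bd <- config$bands[b, ]
      sel <- avg$freq_hz >= bd$f_lo & avg$freq_hz <= bd$f_hi
      band_rows[[paste(cb, bd$band)]] <- tibble::tibble(
        region = cb, band = bd$band,
        coherence = mean(avg$coherence[sel], na.rm = TRUE),
        imaginary = mean(avg$imaginary[sel], na.rm = TRUE))
    }
    sers <- lapply(per_hemi_series, function(s) s$values)
    avg_ser <- Reduce(`+`, sers) / length(sers)
    vals <- avg_ser[is.finite(avg_ser)]
    shape_rows[[paste0("coh_", cb)]] <- dplyr::mutate(
      distribution_shape(vals), target = cb, kind = "theta_coherence",
      .before = 1)
    if (!is.null(speed)) {
      ser_tr <- new_signal_trace(avg_ser, 1 / config$step,
                                 per_hemi_series[[1]]$t0,
                                 label = cb, units = "coherence")
      bt <- speed_correlation_bootstrap(ser_tr, speed, mask = analysis_mask,
                                        n_shuffles = config$n_shuffles,
                                        alpha = config$alpha,
                                        seed = config$seed + 1L)
      cor_rows[[paste0("coh_", cb)]] <- dplyr::mutate(
        tidy(bt), target = cb, kind = "theta_coherence", .before = 1)
    }
  }

  structure(
    list(empty = FALSE,
         spectra = dplyr::bind_rows(spectra),
         coherence = dplyr::bind_rows(coh_rows),
         band_summary = dplyr::bind_rows(band_rows),
         shape = dplyr::bind_rows(shape_rows),
         speed_correlation = dplyr::bind_rows(cor_rows),
         active_s = interval_total(analysis_mask),
         params = config_params(config)),
    class = "homecage_result")
}

#' Linear-track analysis
#'
#' Runs the goal-directed workflow on one session bundle: conditioning,
#' artifact and peri-reward-stimulation exclusion (±0.5 s), run
#' segmentation between successive rewards, distance-from-reward profiles
#' (1 cm bins, occupancy-normalised) for speed, per-channel theta power and
#' per-region theta coherence (magnitude and imaginary, hemisphere-averaged),
#' pooled theta coherence over the approach window, and speed-correlation
#' bootstraps.
#'
#' @param bundle A `session_bundle` with tracking and reward events.
#' @param config An [analysis_config()].
#' @return A named list (class `lineartrack_result`): `runs`,
#'   `speed_profile`, `power_profiles`, `coherence_profiles`, `pooled`,
#'   `speed_correlation`, `n_rewards`, `params`, `empty`.
#' @export
run_linear_track <- function(bundle, config = analysis_config()) {
  roles <- bundle_roles(bundle)
  hips <- hippocampal_labels(roles)
  cbs <- cerebellar_labels(roles)
  if (is.null(bundle$tracking) || is.null(bundle$events$reward)) {
    stop("linear-track analysis needs tracking and reward events", call. = FALSE)
  }
  rewards <- bundle$events$reward
  track_length <- bundle$metadata$track_length %||% 100
  if (nrow(rewards) < 2) {
    warning("fewer than 2 rewards: no runs to analyse")
    return(structure(list(empty = TRUE, n_rewards = nrow(rewards),
                          params = config_params(config)),
                     class = "lineartrack_result"))
  }
  staged <- standardize_notch_bundle(bundle, config)
  clean <- detrend_bundle(staged, config)
  span <- trace_span(clean[[1]])
  artifacts <- combined_artifacts(staged, clean, config)
  peristim <- build_exclusion_mask(rewards, pad = config$peristim_pad_s,
                                   total = interval_set(span[1], span[2]))
  exclude <- interval_union(artifacts, peristim)
  theta <- theta_band_of(config)
  runs <- segment_runs(bundle$tracking, rewards, track_length = track_length,
                       goal_offset = bundle$metadata$goal_zone_offset %||% 10)
  speed <- compute_speed(bundle$tracking, out_rate = config$speed_rate)

  speed_profile <- bin_by_distance(speed, bundle$tracking, runs,
                                   track_length = track_length,
                                   bin_width = config$bin_cm)

  power_profiles <- list(); cor_rows <- list()
  for (lab in names(clean)) {
    sg <- multitaper_spectrogram(clean[[lab]], window = config$window,
                                 step = config$step,
                                 n_tapers = config$n_tapers,
                                 exclude = exclude)
    bs <- band_series(sg, theta)
    prof <- bin_by_distance(bs, bundle$tracking, runs,
                            track_length = track_length,
                            bin_width = config$bin_cm)
    power_profiles[[lab]] <- dplyr::mutate(prof, channel = lab, .before = 1)
    bt <- try(speed_correlation_bootstrap(bs, speed,
                                          n_shuffles = config$n_shuffles,
                                          alpha = config$alpha,
                                          seed = config$seed), silent = TRUE)
    if (!inherits(bt, "try-error")) {
      cor_rows[[lab]] <- dplyr::mutate(tidy(bt), target = lab,
                                       kind = "theta_power", .before = 1)
    }
  }

  coh_profiles <- list(); pooled_rows <- list()
  for (cb in cbs) {
    mag_series <- list(); imag_series <- list()
    for (hp in hips) {
      cs <- pair_cross_spectra(clean[[hp]], clean[[cb]], config, exclude)
      coh_win <- cs$sab / sqrt(cs$saa * cs$sbb)
      fsel <- cs$freqs >= theta[1] & cs$freqs <= theta[2]
      mag <- rowMeans(Mod(coh_win[, fsel, drop = FALSE]))
      ima <- rowMeans(Im(coh_win[, fsel, drop = FALSE]))
      mag[!cs$good] <- NA_real_
      ima[!cs$good] <- NA_real_
      mag_series[[hp]] <- new_signal_trace(mag, 1 / config$step,
                                           cs$centers[1], cb, "coherence")
      imag_series[[hp]] <- new_signal_trace(ima, 1 / config$step,
                                            cs$centers[1], cb, "imag")
    }
    avg_mag <- Reduce(`+`, lapply(mag_series, `[[`, "values")) /
      length(mag_series)
    avg_ima <- Reduce(`+`, lapply(imag_series, `[[`, "values")) /
      length(imag_series)
    t0s <- mag_series[[1]]$t0
    mag_tr <- new_signal_trace(avg_mag, 1 / config$step, t0s, cb, "coherence")
    ima_tr <- new_signal_trace(avg_ima, 1 / config$step, t0s, cb, "imag")
    pm <- bin_by_distance(mag_tr, bundle$tracking, runs,
                          track_length = track_length,
                          bin_width = config$bin_cm)
    pi_ <- bin_by_distance(ima_tr, bundle$tracking, runs,
                           track_length = track_length,
                           bin_width = config$bin_cm)
    pm$imaginary <- pi_$value
    coh_profiles[[cb]] <- dplyr::mutate(pm, region = cb, .before = 1)
    pooled_rows[[cb]] <- tibble::tibble(
      region = cb,
      theta_coherence = pool_profile(pm, config$pooling_window_cm),
      theta_imaginary = pool_profile(
        distance_profile(pi_$bin_center_cm, pi_$value, pi_$occupancy_s),
        config$pooling_window_cm))
    bt <- try(speed_correlation_bootstrap(mag_tr, speed,
                                          n_shuffles = config$n_shuffles,
                                          alpha = config$alpha,
                                          seed = config$seed + 1L),
              silent = TRUE)
    if (!inherits(bt, "try-error")) {
      cor_rows[[paste0("coh_", cb)]] <- dplyr::mutate(
        tidy(bt), target = cb, kind = "theta_coherence", .before = 1)
    }
  }

  structure(
    list(empty = FALSE, runs = runs,
         n_rewards = nrow(rewards),
         speed_profile = speed_profile,
         power_profiles = dplyr::bind_rows(power_profiles),
         coherence_profiles = dplyr::bind_rows(coh_profiles),
         pooled = dplyr::bind_rows(pooled_rows),
         speed_correlation = dplyr::bind_rows(cor_rows),
         params = config_params(config)),
    class = "lineartrack_result")
}

#' Per-day summary across sessions
#'
#' Averages pooled theta coherence and behavioural counts over the (usually
#' three) sessions of one day.
#'
#' @param results List of `lineartrack_result` objects.
#' @return Tibble with one row per region: mean pooled theta coherence,
#'   mean rewards, number of sessions.
#' @export
summarize_day <- function(results) {
  results <- Filter(function(r) isFALSE(r$empty), results)
  if (length(results) == 0) return(tibble::tibble())
  pooled <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    dplyr::mutate(results[[i]]$pooled, session = i)
  }))
  out <- dplyr::summarise(
    dplyr::group_by(pooled, .data$region),
    theta_coherence = mean(.data$theta_coherence, na.rm = TRUE),
    theta_imaginary = mean(.data$theta_imaginary, na.rm = TRUE),
    n_sessions = dplyr::n(), .groups = "drop")
  out$mean_rewards <- mean(vapply(results, function(r) r$n_rewards,
                                  numeric(1)))
  out
}

#' Save an analysis result as CSV tables
#'
#' Writes every tabular component of a `homecage_result` or
#' `lineartrack_result` through [write_results()], with the configuration as
#' the JSON sidecar.
#'
#' @param result A result object from [run_homecage()] or
#'   [run_linear_track()].
#' @param path Output directory.
#' @return Invisibly, the files written.
#' @export
save_result <- function(result, path) {
  tabs <- Filter(is.data.frame, result)
  write_results(tabs, path, params = result$params)
}
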