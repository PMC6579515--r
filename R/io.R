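#' Write a session bundle to a directory
#'
#' Lays out one session as flat files under `path`: LFP/EMG signals as flat
#' little-endian binary (8-byte doubles), tracking/events/spikes as CSV, and
#' a JSON manifest naming every stream with its kind, format, sample rate,
#' units and MD5 checksum. [read_session()] consumes the same layout, and
#' synthetic sessions written this way are indistinguishable from converted
#' real ones downstream.
#'
#' @param bundle A `session_bundle` (see [generate_session()]).
#' @param path Output directory (created if needed).
#' @param force Overwrite an existing manifest, default `FALSE`.
#' @return The manifest path, invisibly.
#' @export
write_session <- function(bundle, path, force = FALSE) {
  stopifnot(inherits(bundle, "session_bundle") || is.list(bundle))
  manifest_path <- file.path(path, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    stop("manifest already exists at ", path, " (use force = TRUE)", call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  streams <- list()
  for (lab in names(bundle$signals)) {
    tr <- bundle$signals[[lab]]
    fn <- paste0("signal_", lab, ".f64")
    con <- file(file.path(path, fn), "wb")
    writeBin(as.numeric(tr$values), con, size = 8, endian = "little")
    close(con)
    streams[[length(streams) + 1]] <- list(
      name = lab, kind = "lfp", format = "f64le", path = fn,
      sample_rate_hz = tr$sample_rate, t0_s = tr$t0, units = tr$units,
      n_samples = length(tr$values),
      md5 = unname(tools::md5sum(file.path(path, fn))))
  }
  if (!is.null(bundle$tracking)) {
    fn <- "tracking.csv"
    write_csv_plain(bundle$tracking[c("time_s", "x_cm", "y_cm")],
                    file.path(path, fn))
    streams[[length(streams) + 1]] <- list(
      name = "tracking", kind = "tracking", format = "csv", path = fn,
      sample_rate_hz = attr(bundle$tracking, "source_rate") %||% 30,
      units = "cm", n_samples = nrow(bundle$tracking),
      md5 = unname(tools::md5sum(file.path(path, fn))))
  }
  for (nm in names(bundle$events)) {
    fn <- paste0("events_", nm, ".csv")
    write_csv_plain(bundle$events[[nm]]["time_s"], file.path(path, fn))
    streams[[length(streams) + 1]] <- list(
      name = nm, kind = "events", format = "csv", path = fn, units = "s",
      n_samples = nrow(bundle$events[[nm]]),
      md5 = unname(tools::md5sum(file.path(path, fn))))
  }
  if (length(bundle$spikes)) {
    fn <- "spikes.csv"
    allsp <- dplyr::bind_rows(lapply(bundle$spikes, function(s) {
      tibble::tibble(unit_id = s$unit_id, time_s = s$time_s)
    }))
    write_csv_plain(allsp, file.path(path, fn))
    streams[[length(streams) + 1]] <- list(
      name = "spikes", kind = "spikes", format = "csv", path = fn,
      units = "s", n_samples = nrow(allsp),
      md5 = unname(tools::md5sum(file.path(path, fn))))
  }
  manifest <- list(format_version = 1L,
                   metadata = bundle$metadata %||% list(),
                   streams = streams)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_csv_plain <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
}

#' Read a session bundle from a directory
#'
#' Inverse of [write_session()]: loads every stream named in
#' `manifest.json`. Binary signals are validated against the manifest's
#' declared sample count; event streams must be sorted in time unless
#' `lenient = TRUE` (which sorts them with a warning). Missing optional
#' streams (tracking, events, spikes) yield absent fields, not errors.
#'
#' @param path Session directory containing `manifest.json`.
#' @param lenient Sort unsorted event streams instead of failing.
#' @param verify_checksums Validate MD5 checksums, default `TRUE`.
#' @return A `session_bundle`.
#' @export
read_session <- function(path, lenient = FALSE, verify_checksums = TRUE) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", path, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path)
  signals <- list(); events <- list(); spikes <- list(); tracking <- NULL
  for (s in man$streams) {
    fp <- file.path(path, s$path)
    if (!file.exists(fp)) stop("stream '", s$name, "': file missing", call. = FALSE)
    if (isTRUE(verify_checksums) && !is.null(s$md5)) {
      if (unname(tools::md5sum(fp)) != s$md5) {
        stop("stream '", s$name, "': checksum mismatch", call. = FALSE)
      }
    }
    if (s$kind %in% c("lfp", "emg")) {
      if (identical(s$format, "csv")) {
        vals <- utils::read.csv(fp)$value
      } else {
        expect_n <- as.integer(s$n_samples)
        sz <- file.info(fp)$size
        if (sz != 8 * expect_n) {
          stop(sprintf(
            "stream '%s': binary length %d bytes inconsistent with declared %d samples",
            s$name, sz, expect_n), call. = FALSE)
        }
        con <- file(fp, "rb")
        vals <- readBin(con, "double", n = expect_n, size = 8,
                        endian = "little")
        close(con)
      }
      signals[[s$name]] <- signal_trace(vals, s$sample_rate_hz,
                                        t0 = s$t0_s %||% 0,
                                        label = s$name,
                                        units = s$units %||% "")
    } else if (s$kind == "tracking") {
      df <- utils::read.csv(fp)
      if (is.unsorted(df$time_s, strictly = TRUE)) {
        stop("stream 'tracking': times not strictly increasing", call. = FALSE)
      }
      tracking <- tracking_trace(df$time_s, df$x_cm, df$y_cm,
                                 source_rate = s$sample_rate_hz %||% 30)
    } else if (s$kind == "events") {
      df <- utils::read.csv(fp)
      if (nrow(df) && is.unsorted(df$time_s)) {
        if (lenient) {
          warning("stream '", s$name, "': sorting unsorted event times")
          df <- df[order(df$time_s), , drop = FALSE]
        } else {
          stop("stream '", s$name, "': event times not sorted", call. = FALSE)
        }
      }
      events[[s$name]] <- tibble::as_tibble(df)
    } else if (s$kind == "spikes") {
      df <- utils::read.csv(fp)
      for (u in unique(df$unit_id)) {
        tu <- sort(df$time_s[df$unit_id == u])
        spikes[[u]] <- spike_train(u, tu)
      }
    }
  }
  structure(
    list(signals = signals, tracking = tracking, events = events,
         spikes = spikes, metadata = man$metadata, ground_truth = NULL),
    class = "session_bundle")
}

#' Write result tables with a parameter sidecar
#'
#' Each named table becomes `<name>.csv`; `params` is serialised to
#' `params.json` alongside them so every output carries the window, taper,
#' band, and seed settings that produced it. Outputs are deterministic:
#' re-running with identical inputs and parameters reproduces byte-identical
#' files.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if needed).
#' @param params Named list of parameters to record.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(tables, path, params = list()) {
  stopifnot(is.list(tables))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(tables)) {
    fp <- file.path(path, paste0(nm, ".csv"))
    df <- tables[[nm]]
    # drop non-atomic columns; serialise numerics at full precision
    df <- as.data.frame(lapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.17g", col) else col
    }), optional = TRUE, stringsAsFactors = FALSE)
    names(df) <- names(tables[[nm]])
    write_csv_plain(df, fp)
    written <- c(written, fp)
  }
  pj <- file.path(path, "params.json")
  jsonlite::write_json(params, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(written, pj))
}
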