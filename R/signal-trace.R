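#' Uniformly sampled continuous signal
#'
#' A `signal_trace` holds one uniformly sampled continuous signal (an LFP
#' channel, an EMG, or a derived series such as speed or band power) together
#' with its sample rate, time origin and units. Times are seconds from
#' session start; the i-th sample sits at `t0 + (i - 1) / sample_rate`.
#'
#' @param values Numeric vector of samples. Must be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param label Channel label, e.g. `"hpc_left"`.
#' @param units Unit string, e.g. `"z"` or `"cm/s"`.
#'
#' @return An object of class `signal_trace`.
#' @export
#'
#' @examples
#' tr <- signal_trace(sin(2 * pi * 8 * seq(0, 1, by = 1e-3)), sample_rate = 1000)
#' trace_times(tr)[1:3]
signal_trace <- function(values, sample_rate, t0 = 0, label = "", units = "") {
  values <- as.numeric(values)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  structure(
    list(values = values, sample_rate = sample_rate, t0 = t0,
         label = label, units = units),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s: %d samples @ %g Hz, t0 = %g s [%s]\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              length(x$values), x$sample_rate, x$t0, x$units))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param trace A [signal_trace()].
#' @return Numeric vector of sample times (s).
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) / trace$sample_rate
}

#' Duration spanned by a trace
#'
#' Half-open span `[t0, t0 + n/rate)`.
#'
#' @param trace A [signal_trace()].
#' @return Length-2 numeric `(start, end)` in seconds.
#' @export
trace_span <- function(trace) {
  c(trace$t0, trace$t0 + length(trace$values) / trace$sample_rate)
}

#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.signal_trace <- function(x, ...) {
  tibble::tibble(time_s = trace_times(x), value = x$values)
}

#' Sorted, disjoint half-open time intervals
#'
#' `interval_set` represents inclusion/exclusion masks as a set of half-open
#' intervals `[start, end)` in seconds. The constructor sorts and merges
#' overlapping or touching intervals, so the invariant (sorted, disjoint,
#' start < end) always holds.
#'
#' @param start,end Numeric vectors of equal length; each pair must satisfy
#'   `start < end`.
#' @return An `interval_set`: a tibble with columns `start`, `end` and class
#'   `interval_set`.
#' @export
#'
#' @examples
#' interval_set(c(0, 1.5, 1), c(1, 3, 2))   # merges [1,2) and [1.5,3)
interval_set <- function(start = numeric(0), end = numeric(0)) {
  if (length(start) != length(end)) stop("start/end length mismatch", call. = FALSE)
  if (any(!is.finite(start)) || any(!is.finite(end))) stop("intervals must be finite", call. = FALSE)
  if (any(end <= start)) stop("each interval needs start < end", call. = FALSE)
  if (length(start) > 1) {
    o <- order(start)
    start <- start[o]; end <- end[o]
    ms <- start[1]; me <- end[1]; outs <- numeric(0); oute <- numeric(0)
    for (i in seq_along(start)[-1]) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        outs <- c(outs, ms); oute <- c(oute, me)
        ms <- start[i]; me <- end[i]
      }
    }
    start <- c(outs, ms); end <- c(oute, me)
  }
  out <- tibble::tibble(start = as.numeric(start), end = as.numeric(end))
  class(out) <- c("interval_set", class(out))
  out
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d interval(s), total %.3f s\n",
              nrow(x), interval_total(x)))
  if (nrow(x)) print(tibble::as_tibble(unclass_intervals(x)))
  invisible(x)
}

unclass_intervals <- function(x) {
  class(x) <- setdiff(class(x), "interval_set")
  x
}

#' Total duration covered by an interval set
#' @param x An [interval_set()].
#' @return Total covered time (s).
#' @export
interval_total <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}

#' Interval-set algebra
#'
#' Union, intersection and complement of half-open interval sets. The
#' complement is taken within an explicit span `[span[1], span[2])`.
#'
#' @param a,b [interval_set()] objects.
#' @param span Length-2 numeric giving the universe for `interval_complement`.
#' @return An [interval_set()].
#' @name interval-algebra
NULL

#' @rdname interval-algebra
#' @export
interval_union <- function(a, b) {
  interval_set(c(a$start, b$start), c(a$end, b$end))
}

#' @rdname interval-algebra
#' @export
interval_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(interval_set())
  ss <- numeric(0); ee <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a$start[i], b$start[j])
    hi <- min(a$end[i], b$end[j])
    if (lo < hi) { ss <- c(ss, lo); ee <- c(ee, hi) }
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  interval_set(ss, ee)
}

#' @rdname interval-algebra
#' @export
interval_complement <- function(a, span) {
  stopifnot(length(span) == 2, span[1] < span[2])
  a <- interval_intersect(a, interval_set(span[1], span[2]))
  if (nrow(a) == 0) return(interval_set(span[1], span[2]))
  edges_lo <- c(span[1], a$end)
  edges_hi <- c(a$start, span[2])
  keep <- edges_lo < edges_hi
  interval_set(edges_lo[keep], edges_hi[keep])
}

#' Membership of time points in an interval set
#'
#' @param x An [interval_set()].
#' @param times Numeric vector of times (s).
#' @return Logical vector: `TRUE` where a time falls inside some `[start, end)`.
#' @export
interval_contains <- function(x, times) {
  if (nrow(x) == 0) return(rep(FALSE, length(times)))
  idx <- findInterval(times, x$start)
  idx > 0 & times < x$end[pmax(idx, 1L)]
}
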