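#' Bootstrap shuffle null for speed correlations
#'
#' Spearman rank correlation between an instantaneous series (band power or
#' band coherence on the 10 Hz grid) and instantaneous speed, compared
#' against a null built by randomly permuting the speed samples. The
#' observed correlation is declared significant when it falls outside the
#' empirical `alpha/2` and `1 - alpha/2` quantiles of the shuffled
#' correlations (0.025/0.975 for the default `alpha = 0.05`).
#'
#' The whole-vector permutation null is exact for exchangeable samples;
#' strongly autocorrelated series widen the true null beyond it (see the
#' package vignette). `block_s > 0` switches to a circular block shuffle as
#' a conservative alternative.
#'
#' @param series A [signal_trace()] (or numeric vector) on the same grid as
#'   `speed`.
#' @param speed A [signal_trace()] of speed (or numeric vector).
#' @param mask Optional [interval_set()] selecting samples (e.g. active
#'   movement); applied to the series' time grid.
#' @param n_shuffles Number of permutations, default 1000.
#' @param alpha Two-sided level, default 0.05.
#' @param seed Integer seed for the permutations.
#' @param block_s Block length (s) for the optional block shuffle; 0 =
#'   full permutation (default).
#' @param min_samples Minimum retained samples, default 40.
#' @return A `speed_cor_boot` object: list with `rho_observed`,
#'   `null_values`, `lower`, `upper`, `significant`, `n_samples`, `seed`.
#' @export
speed_correlation_bootstrap <- function(series, speed, mask = NULL,
                                        n_shuffles = 1000, alpha = 0.05,
                                        seed = 1L, block_s = 0,
                                        min_samples = 40) {
  if (inherits(series, "signal_trace")) {
    times <- trace_times(series)
    s_rate <- series$sample_rate
    x <- series$values
  } else {
    x <- as.numeric(series); times <- seq_along(x); s_rate <- 1
  }
  y <- if (inherits(speed, "signal_trace")) {
    if (inherits(series, "signal_trace")) {
      stats::approx(trace_times(speed), speed$values, xout = times,
                    rule = 2)$y
    } else speed$values
  } else as.numeric(speed)
  if (length(x) != length(y)) stop("series and speed must share the grid", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(mask)) keep <- keep & interval_contains(mask, times)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_samples) stop(sprintf("only %d retained samples (< %d)", n, min_samples), call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant series or speed: Spearman correlation undefined", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  null_values <- with_seed_local(seed, {
    if (block_s > 0) {
      blk <- max(1L, round(block_s * s_rate))
      vapply(seq_len(n_shuffles), function(i) {
        shift <- sample.int(n, 1)
        nb <- ceiling(n / blk)
        ord <- unlist(lapply(sample.int(nb), function(b) {
          seq((b - 1) * blk + 1, min(b * blk, n))
        }), use.names = FALSE)
        ord <- ((ord + shift - 1) %% n) + 1
        sum(rxc * ryc[ord]) / denom
      }, numeric(1))
    } else {
      vapply(seq_len(n_shuffles), function(i) {
        sum(rxc * ryc[sample.int(n)]) / denom
      }, numeric(1))
    }
  })
  qs <- stats::quantile(null_values, c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
  structure(
    list(rho_observed = rho, null_values = null_values,
         lower = qs[1], upper = qs[2],
         significant = rho < qs[1] || rho > qs[2],
         n_samples = n, n_shuffles = n_shuffles, alpha = alpha, seed = seed),
    class = "speed_cor_boot"
  )
}

#' @export
print.speed_cor_boot <- function(x, ...) {
  cat(sprintf(
    "<speed_cor_boot> rho = %.3f, null limits [%.3f, %.3f] (n = %d, %d shuffles)%s\n",
    x$rho_observed, x$lower, x$upper, x$n_samples, x$n_shuffles,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.speed_cor_boot <- function(x, ...) {
  tibble::tibble(rho = x$rho_observed, lower = x$lower, upper = x$upper,
                 significant = x$significant, n_samples = x$n_samples,
                 n_shuffles = x$n_shuffles, alpha = x$alpha)
}

#' @exportS3Method generics::glance
glance.speed_cor_boot <- function(x, ...) tidy(x)

#' Distribution-shape summary
#'
#' Adjusted Fisher-Pearson sample skewness, a standard normality test
#' (Shapiro-Wilk for n <= 5000, Anderson-Darling above that limit), and a
#' fixed-bin histogram summary for descriptive modality inspection of
#' instantaneous power/coherence distributions.
#'
#' @param x Numeric values (n >= 8).
#' @param n_bins Histogram bins for the modality summary, default 50.
#' @return A tibble (`shape_summary`) with `n`, `skewness`, `normality_p`,
#'   `normality_test`, `modality_note`; the histogram is attached as
#'   attribute `"histogram"`.
#' @export
distribution_shape <- function(x, n_bins = 50) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("need at least 8 finite values", call. = FALSE)
  m <- mean(x); s <- stats::sd(x)
  g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  if (n <= 5000) {
    ht <- stats::shapiro.test(x)
    test <- "shapiro-wilk"
  } else {
    ht <- nortest::ad.test(x)
    test <- "anderson-darling"
  }
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  # modality from a smooth density estimate: histogram bin noise would
  # otherwise masquerade as extra modes
  de <- stats::density(x)
  dens <- de$y
  left <- c(-Inf, dens[-length(dens)])
  right <- c(dens[-1], -Inf)
  peaks <- sum(dens >= left & dens > right & dens > 0.2 * max(dens))
  note <- if (peaks <= 1) "unimodal histogram" else sprintf("%d histogram modes", peaks)
  out <- tibble::tibble(n = n, skewness = skew,
                        normality_p = unname(ht$p.value),
                        normality_test = test, modality_note = note)
  class(out) <- c("shape_summary", class(out))
  attr(out, "histogram") <- tibble::tibble(mid = h$mids, density = h$density)
  out
}
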