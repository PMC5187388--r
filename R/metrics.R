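series_values <- function(x) {
  if (inherits(x, c("intensity_series", "firing_rate_series"))) x$values
  else if (is.numeric(x)) as.numeric(x)
  else stopf("expected a series object or numeric vector")
}

series_dt <- function(x) {
  if (inherits(x, c("intensity_series", "firing_rate_series"))) x$dt else NA_real_
}

#' Autocorrelation function of a series
#'
#' Normalised autocorrelation
#' \deqn{AC(\tau) = \frac{1}{T}\sum_t (x(t)-\mu_X)(x(t+\tau)-\mu_X) / \sigma_X^2}
#' for lags 0..`max_lag`, where the mean and variance are taken over the full
#' series in a single pass (not per window). Values lie in \[-1, 1\] and
#' AC(0) = 1 for any non-constant series.
#'
#' A constant series has \eqn{\sigma_X^2 = 0} and the quotient is undefined;
#' by convention the result is AC = 0 at every lag >= 0 and the returned
#' object carries `degenerate = TRUE`. This is the natural reading for a
#' sensor output pinned at the spontaneous rate: a constant output transmits
#' nothing.
#'
#' @param series An [intensity_series()], [firing_rate_series()], or numeric
#'   vector.
#' @param max_lag Largest lag (in samples) to evaluate; must be smaller than
#'   the series length.
#' @return An object of class `ac_function` with fields `lags` (sample
#'   counts), `lag_time` (lags times dt, if known), `values`, `degenerate`.
#' @examples
#' s <- generate_ou_series(env_config(n_samples = 5000, seed = 1))
#' acfun <- autocorrelation_function(s, max_lag = 30)
#' @export
autocorrelation_function <- function(series, max_lag = 50) {
  x <- series_values(series)
  check_number(max_lag, "max_lag", lower = 1, integerish = TRUE)
  if (max_lag >= length(x))
    stopf("`max_lag` (%d) must be smaller than the series length (%d)",
          max_lag, length(x))
  degenerate <- stats::sd(x) == 0
  values <- if (degenerate) rep(0, max_lag + 1)
    else as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)
  dt <- series_dt(series)
  structure(list(lags = 0:max_lag,
                 lag_time = if (is.na(dt)) NULL else (0:max_lag) * dt,
                 values = values, degenerate = degenerate),
            class = "ac_function")
}

#' @export
print.ac_function <- function(x, ...) {
  cat(sprintf("Autocorrelation function: lags 0..%d%s\n",
              max(x$lags), if (x$degenerate) " (degenerate: constant series)"
              else ""))
  cat(sprintf("  AC(1) = %.3f, mean over positive lags = %.4f\n",
              x$values[2], mean(x$values[-1])))
  invisible(x)
}

#' @export
as.data.frame.ac_function <- function(x, ...) {
  data.frame(lag = x$lags,
             lag_time = if (is.null(x$lag_time)) NA else x$lag_time,
             ac = x$values)
}

#' Mean autocorrelation
#'
#' The model's information proxy: the autocorrelation function averaged over
#' the evaluated positive lags, \eqn{\overline{AC} = N^{-1}\sum_{\tau=1}^N
#' AC(\tau)}. Lag 0 is excluded. Given a series instead of an `ac_function`,
#' the AC function is computed first with `max_lag` lags.
#'
#' The number of lags N is a tuning parameter; the default 50 lags at the
#' environment's native sampling (dt = 0.1) covers five correlation times of
#' the OU input, by which point the input AC has decayed to below 0.01.
#'
#' @param x An `ac_function`, a series object, or a numeric vector.
#' @param max_lag Number of positive lags N when `x` is a series.
#' @return A single number in \[-1, 1\].
#' @examples
#' s <- generate_ou_series(env_config(n_samples = 5000, seed = 1))
#' mean_autocorrelation(s, max_lag = 50)
#' @export
mean_autocorrelation <- function(x, max_lag = 50) {
  if (!inherits(x, "ac_function"))
    x <- autocorrelation_function(x, max_lag = max_lag)
  v <- x$values[x$lags >= 1]
  if (length(v) < 1L) stopf("no positive lags to average over")
  mean(v)
}

#' Histogram estimate of mutual information
#'
#' Plug-in estimator of the mutual information (in bits) between two equal-
#' length series from a 2-D equal-width histogram:
#' \deqn{MI(X;Y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)\,p(y)}}
#' Bin ranges are clipped to mean +/- 5 sd of each series so single outliers
#' cannot stretch the bins. The estimator is simple and positively biased at
#' finite sample size; it is adequate for locating the maximum of a resonance
#' curve, which needs only the argmax, not unbiased MI values.
#'
#' @param x,y Series objects or numeric vectors of equal length.
#' @param n_bins Histogram resolution per axis (>= 2).
#' @return An object of class `mi_estimate` with fields `value` (bits,
#'   >= 0), `n_bins_x`, `n_bins_y`.
#' @examples
#' s <- generate_ou_series(env_config(n_samples = 2000, seed = 1))
#' r <- respond(s, sensor_params(), noise_model(4), seed = 2)
#' mutual_information(s, r)
#' @export
mutual_information <- function(x, y, n_bins = 64) {
  xv <- series_values(x); yv <- series_values(y)
  if (length(xv) != length(yv))
    stopf("`x` (%d) and `y` (%d) must have equal length",
          length(xv), length(yv))
  check_number(n_bins, "n_bins", lower = 2, integerish = TRUE)
  value <- if (stats::sd(xv) == 0 || stats::sd(yv) == 0) 0 else {
    ix <- bin_index(xv, n_bins)
    iy <- bin_index(yv, n_bins)
    joint <- table(factor(ix, levels = seq_len(n_bins)),
                   factor(iy, levels = seq_len(n_bins))) / length(xv)
    px <- rowSums(joint); py <- colSums(joint)
    pos <- joint > 0
    sum(joint[pos] * log2(joint[pos] / outer(px, py)[pos]))
  }
  structure(list(value = max(value, 0), n_bins_x = n_bins, n_bins_y = n_bins),
            class = "mi_estimate")
}

bin_index <- function(v, n_bins) {
  m <- mean(v); s <- stats::sd(v)
  lo <- max(min(v), m - 5 * s); hi <- min(max(v), m + 5 * s)
  v <- pmin(pmax(v, lo), hi)
  idx <- findInterval(v, seq(lo, hi, length.out = n_bins + 1),
                      rightmost.closed = TRUE, all.inside = TRUE)
  idx
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("Mutual information: %.4f bits (%d x %d bins)\n",
              x$value, x$n_bins_x, x$n_bins_y))
  invisible(x)
}
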