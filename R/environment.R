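#' Configuration of the simulated acoustic environment
#'
#' The model's "standard acoustic environment" is a Gaussian distribution of
#' sound intensity levels (in dB SPL) with mean `mu_I` = 40 dB and standard
#' deviation `sigma_I` = 25 dB, sampled as a temporally autocorrelated
#' trajectory by an Ornstein-Uhlenbeck (OU) process with unit relaxation rate,
#' or as an i.i.d. control series with the same marginal distribution.
#'
#' @param mu_I Mean intensity, dB SPL.
#' @param sigma_I Intensity standard deviation, dB. May be 0, which gives a
#'   constant series at `mu_I`.
#' @param dt Time step between samples, in units of the OU correlation time.
#' @param n_samples Number of samples to generate (>= 2).
#' @param seed Integer RNG seed, or `NULL` to use the global RNG.
#' @param I0 Initial intensity, dB SPL. Default `NULL` draws the first sample
#'   from the stationary distribution N(`mu_I`, `sigma_I`^2), so the whole
#'   series is stationary and no burn-in is needed.
#'
#' @return An object of class `env_config`.
#' @seealso [generate_ou_series()], [generate_iid_series()]
#' @examples
#' cfg <- env_config(n_samples = 1000, seed = 1)
#' series <- generate_ou_series(cfg)
#' @export
env_config <- function(mu_I = 40, sigma_I = 25, dt = 0.1, n_samples = 2e5,
                       seed = NULL, I0 = NULL) {
  check_number(mu_I, "mu_I")
  check_number(sigma_I, "sigma_I", lower = 0)
  check_number(dt, "dt", lower = .Machine$double.eps)
  check_number(n_samples, "n_samples", lower = 2, integerish = TRUE)
  check_number(seed, "seed", allow_null = TRUE, integerish = TRUE)
  check_number(I0, "I0", allow_null = TRUE)
  structure(
    list(mu_I = mu_I, sigma_I = sigma_I, dt = dt,
         n_samples = as.integer(n_samples), seed = seed, I0 = I0),
    class = "env_config")
}

#' @export
print.env_config <- function(x, ...) {
  cat("Acoustic environment config\n")
  cat(sprintf("  intensity ~ N(%g dB, %g dB sd), dt = %g, n = %d\n",
              x$mu_I, x$sigma_I, x$dt, x$n_samples))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Gaussian probability density of sound intensity levels
#'
#' Density (per dB) of the environment's intensity distribution,
#' \eqn{p_I(I) = (2\pi\sigma_I^2)^{-1/2} \exp(-(I-\mu_I)^2 / 2\sigma_I^2)}.
#'
#' @param I Intensity (dB SPL); vectorised.
#' @param mu_I Mean intensity, dB SPL.
#' @param sigma_I Standard deviation, dB; must be strictly positive.
#' @return Probability density, per dB.
#' @examples
#' gaussian_intensity_pdf(40) # 1 / (25 * sqrt(2 * pi))
#' @export
gaussian_intensity_pdf <- function(I, mu_I = 40, sigma_I = 25) {
  check_number(mu_I, "mu_I")
  check_number(sigma_I, "sigma_I", lower = .Machine$double.eps)
  exp(-(I - mu_I)^2 / (2 * sigma_I^2)) / sqrt(2 * pi * sigma_I^2)
}

#' Intensity time series
#'
#' Container for a sampled trajectory of sound intensity levels. Values are in
#' dB SPL and may be negative (the dB scale is unbounded below).
#'
#' @param values Numeric vector of intensities, dB SPL (length >= 2, finite).
#' @param dt Time step, model time units.
#' @return An object of class `intensity_series`.
#' @export
intensity_series <- function(values, dt) {
  if (!is.numeric(values) || length(values) < 2L || !all(is.finite(values)))
    stopf("`values` must be a finite numeric vector of length >= 2")
  check_number(dt, "dt", lower = .Machine$double.eps)
  structure(list(values = as.numeric(values), dt = dt),
            class = "intensity_series")
}

#' @export
print.intensity_series <- function(x, ...) {
  cat(sprintf("Intensity series: %d samples, dt = %g\n",
              length(x$values), x$dt))
  cat(sprintf("  mean %.2f dB, sd %.2f dB, range [%.1f, %.1f] dB\n",
              mean(x$values), stats::sd(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.intensity_series <- function(x, ...) {
  data.frame(time = (seq_along(x$values) - 1) * x$dt,
             intensity_db = x$values)
}

#' Generate an Ornstein-Uhlenbeck intensity series
#'
#' Simulates the standard acoustic environment: an OU process with unit
#' relaxation rate, stationary mean `mu_I` and stationary variance
#' `sigma_I`^2, so the marginal distribution equals the Gaussian intensity
#' distribution and the autocorrelation decays as exp(-tau) in model time
#' units. The exact discrete-time transition
#' \deqn{I_{t+dt} = \mu_I + (I_t - \mu_I) e^{-dt} +
#'       \sigma_I \sqrt{1 - e^{-2 dt}}\, \xi,\quad \xi \sim N(0,1)}
#' is used rather than Euler-Maruyama; it is unconditionally stable and exact
#' for any time step.
#'
#' @param config An [env_config()].
#' @return An [intensity_series()].
#' @examples
#' s <- generate_ou_series(env_config(n_samples = 5000, seed = 42))
#' mean(s$values) # close to 40
#' @export
generate_ou_series <- function(config) {
  stopifnot(inherits(config, "env_config"))
  n <- config$n_samples
  phi <- exp(-config$dt)
  sd_step <- config$sigma_I * sqrt(1 - phi^2)
  with_seed(config$seed, {
    i0 <- if (is.null(config$I0))
      stats::rnorm(1, config$mu_I, config$sigma_I) else config$I0
    innov <- stats::rnorm(n - 1, 0, sd_step)
    dev <- stats::filter(innov, phi, method = "recursive", init = i0 - config$mu_I)
    intensity_series(config$mu_I + c(i0 - config$mu_I, as.numeric(dev)),
                     config$dt)
  })
}

#' Generate an uncorrelated (i.i.d.) intensity series
#'
#' Control condition: independent draws from the same Gaussian marginal
#' N(`mu_I`, `sigma_I`^2) as the OU environment, so the two series have
#' identical probability density functions but entirely different
#' autocorrelation functions.
#'
#' @inheritParams generate_ou_series
#' @return An [intensity_series()].
#' @export
generate_iid_series <- function(config) {
  stopifnot(inherits(config, "env_config"))
  with_seed(config$seed,
    intensity_series(stats::rnorm(config$n_samples, config$mu_I,
                                  config$sigma_I),
                     config$dt))
}

#' Write / read an intensity or firing-rate series as CSV
#'
#' Two-column CSV (`time`, `intensity_db` or `rate_hz`), with an optional JSON
#' sidecar (`<path>.json`) holding the generating configuration.
#'
#' @param series An `intensity_series` or `firing_rate_series`.
#' @param path Output CSV path.
#' @param config Optional [env_config()] written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, config = NULL) {
  df <- as.data.frame(series)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$I0 <- if (is.null(cfg$I0)) NA else cfg$I0
    cfg$seed <- if (is.null(cfg$seed)) NA else cfg$seed
    jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_series_csv
#' @return For `read_series_csv`, the reconstructed series object.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  dt <- if (nrow(df) > 1) df$time[2] - df$time[1] else 1
  if ("rate_hz" %in% names(df))
    return(structure(list(values = df$rate_hz, dt = dt),
                     class = "firing_rate_series"))
  intensity_series(df$intensity_db, dt)
}
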