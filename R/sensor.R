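#' Auditory-nerve sensor parameters
#'
#' The sensor maps sound intensity (dB SPL) to an instantaneous auditory-nerve
#' firing rate (Hz) through an infomax rate-intensity function: below the
#' hearing threshold `I_theta` the output is the spontaneous rate `f_sp`;
#' above it the rate is proportional to the cumulative distribution function
#' of the intensity distribution the fibre is adapted to, rising to `f_max`.
#' Hearing loss is modelled purely as an elevation of `I_theta`, with all
#' other parameters unchanged.
#'
#' The adapted distribution (`mu_I`, `sigma_I`) stays fixed at the standard
#' environment even when the threshold is raised: no re-adaptation after
#' cochlear damage is assumed, so rate-intensity curves for all thresholds
#' share the same CDF shape and asymptote.
#'
#' @param I_theta Hearing threshold, dB SPL.
#' @param f_sp Spontaneous firing rate, Hz (>= 0).
#' @param f_max Maximum firing rate, Hz (> `f_sp`).
#' @param mu_I,sigma_I Mean / sd (dB) of the intensity distribution the
#'   response function is adapted to.
#' @return An object of class `sensor_params`.
#' @examples
#' p <- sensor_params()          # healthy fibre, 0 dB threshold
#' p40 <- sensor_params(I_theta = 40)  # 40 dB hearing loss
#' @export
sensor_params <- function(I_theta = 0, f_sp = 50, f_max = 250,
                          mu_I = 40, sigma_I = 25) {
  check_number(I_theta, "I_theta")
  check_number(f_sp, "f_sp", lower = 0)
  check_number(f_max, "f_max")
  if (f_max <= f_sp) stopf("`f_max` (%g) must exceed `f_sp` (%g)", f_max, f_sp)
  check_number(mu_I, "mu_I")
  check_number(sigma_I, "sigma_I", lower = .Machine$double.eps)
  structure(list(I_theta = I_theta, f_sp = f_sp, f_max = f_max,
                 mu_I = mu_I, sigma_I = sigma_I),
            class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat(sprintf(
    "Sensor: threshold %g dB SPL, rates %g-%g Hz, adapted to N(%g, %g^2) dB\n",
    x$I_theta, x$f_sp, x$f_max, x$mu_I, x$sigma_I))
  cat(sprintf("  P_sp (sub-threshold mass) = %.4f\n",
              spontaneous_probability(x)))
  invisible(x)
}

#' Injected internal-noise model
#'
#' White Gaussian noise with fixed zero mean and tunable variance
#' `sigma_n_sq` (dB^2), drawn independently at every time sample and summed
#' with the acoustic input before thresholding.
#'
#' @param sigma_n_sq Noise variance, dB^2 (>= 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_n_sq = 0) {
  check_number(sigma_n_sq, "sigma_n_sq", lower = 0)
  structure(list(sigma_n_sq = sigma_n_sq), class = "noise_model")
}

#' Probability of spontaneous activity
#'
#' The mass of the adapted intensity distribution below the hearing
#' threshold, \eqn{P_{sp} = \Phi((I_\theta - \mu_I)/\sigma_I)}: the fraction
#' of environmental sound intensities that evoke only spontaneous firing.
#'
#' @param params A [sensor_params()].
#' @return Probability in \[0, 1\].
#' @examples
#' spontaneous_probability(sensor_params()) # Phi(-1.6), about 0.055
#' @export
spontaneous_probability <- function(params) {
  stopifnot(inherits(params, "sensor_params"))
  stats::pnorm((params$I_theta - params$mu_I) / params$sigma_I)
}

#' Infomax rate-intensity function
#'
#' Firing rate as a function of sound intensity:
#' \deqn{f(I) = f_{sp} \quad (I < I_\theta)}
#' \deqn{f(I) = f_{sp} + (f_{max}-f_{sp})
#'   \frac{\Phi((I-\mu_I)/\sigma_I) - \Phi((I_\theta-\mu_I)/\sigma_I)}
#'        {1 - P_{sp}} \quad (I \ge I_\theta)}
#' The normalised CDF form means the fibre devotes equal rate range to equally
#' probable intensities (infomax coding). The function is continuous at the
#' threshold, non-decreasing, and saturates at `f_max`. The analytic Gaussian
#' CDF is used, not an empirical histogram.
#'
#' @param I Sound intensity, dB SPL; vectorised.
#' @param params A [sensor_params()].
#' @return Firing rate(s), Hz, in \[`f_sp`, `f_max`\].
#' @examples
#' rate_intensity(c(-10, 40, 1000), sensor_params())
#' @export
rate_intensity <- function(I, params) {
  stopifnot(inherits(params, "sensor_params"))
  p_sp <- spontaneous_probability(params)
  r <- params$f_sp + (params$f_max - params$f_sp) *
    (stats::pnorm((I - params$mu_I) / params$sigma_I) - p_sp) / (1 - p_sp)
  ifelse(I < params$I_theta, params$f_sp, r)
}

#' Firing-rate series
#'
#' @param values Firing rates, Hz.
#' @param dt Time step, model time units.
#' @return An object of class `firing_rate_series`.
#' @export
firing_rate_series <- function(values, dt) {
  if (!is.numeric(values) || length(values) < 2L || !all(is.finite(values)))
    stopf("`values` must be a finite numeric vector of length >= 2")
  check_number(dt, "dt", lower = .Machine$double.eps)
  structure(list(values = as.numeric(values), dt = dt),
            class = "firing_rate_series")
}

#' @export
print.firing_rate_series <- function(x, ...) {
  cat(sprintf("Firing-rate series: %d samples, dt = %g, mean %.1f Hz\n",
              length(x$values), x$dt, mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.firing_rate_series <- function(x, ...) {
  data.frame(time = (seq_along(x$values) - 1) * x$dt, rate_hz = x$values)
}

#' Noisy sensor response to an intensity series
#'
#' The stochastic-resonance pathway: at every time sample an independent
#' internal-noise value n ~ N(0, `sigma_n_sq`) is summed with the acoustic
#' input before thresholding, and the rate-intensity function is evaluated at
#' I(t) + n — both the threshold comparison and the CDF argument use the
#' summed input. With `sigma_n_sq = 0` this reduces exactly to mapping
#' [rate_intensity()] over the series. Total inputs are not clamped below:
#' the rate function already saturates at `f_sp`.
#'
#' @param series An [intensity_series()].
#' @param params A [sensor_params()].
#' @param noise A [noise_model()], or a single number taken as `sigma_n_sq`.
#' @param seed Integer RNG seed, or `NULL`.
#' @return A [firing_rate_series()].
#' @examples
#' env <- env_config(n_samples = 1000, seed = 1)
#' resp <- respond(generate_ou_series(env), sensor_params(I_theta = 20),
#'                 noise_model(25), seed = 2)
#' @export
respond <- function(series, params, noise = noise_model(0), seed = NULL) {
  stopifnot(inherits(series, "intensity_series"),
            inherits(params, "sensor_params"))
  if (is.numeric(noise)) noise <- noise_model(noise)
  stopifnot(inherits(noise, "noise_model"))
  x <- series$values
  if (noise$sigma_n_sq > 0) {
    x <- x + with_seed(seed,
      stats::rnorm(length(x), 0, sqrt(noise$sigma_n_sq)))
  }
  firing_rate_series(rate_intensity(x, params), series$dt)
}
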