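#' Default injected-noise grid
#'
#' 60 noise levels with the noise *standard deviation* equally spaced from 0
#' to `max_factor` times the environment sd (default 0 to 75 dB), returned as
#' variances (dB^2). Equal spacing in sigma_n rather than sigma_n^2 resolves
#' optima at both small and large thresholds.
#'
#' @param sigma_I Environment standard deviation, dB.
#' @param n_levels Number of grid levels.
#' @param max_factor Largest noise sd as a multiple of `sigma_I`.
#' @return Strictly increasing vector of noise variances (dB^2) starting at 0.
#' @export
noise_grid_default <- function(sigma_I = 25, n_levels = 60, max_factor = 3) {
  check_number(sigma_I, "sigma_I", lower = .Machine$double.eps)
  check_number(n_levels, "n_levels", lower = 2, integerish = TRUE)
  check_number(max_factor, "max_factor", lower = .Machine$double.eps)
  seq(0, max_factor * sigma_I, length.out = n_levels)^2
}

#' Resonance curve: information objective versus injected-noise level
#'
#' For every noise variance on the grid the sensor response to an
#' environment realisation is simulated and the mean output autocorrelation
#' (and optionally the input-output mutual information) is evaluated; the
#' located maximum defines the optimal stochastic-resonance noise level.
#'
#' By default all grid points share one environment realisation and one
#' standard-normal noise vector scaled to each grid level (common random
#' numbers). This makes the curve smooth and the located argmax reproducible:
#' differences between grid points then reflect the noise level, not
#' Monte-Carlo re-sampling. `independent = TRUE` instead draws a fresh
#' realisation per grid point, so curve roughness shows the raw Monte-Carlo
#' error; with a nearly flat objective the argmax of such a curve is
#' dominated by sampling jitter, which is why it is not the default.
#'
#' @param env An [env_config()] describing the acoustic environment.
#' @param params A [sensor_params()].
#' @param noise_grid Increasing vector of noise variances (dB^2) including 0;
#'   default [noise_grid_default()] scaled to `env$sigma_I` (or to
#'   `params$sigma_I` when the environment is constant).
#' @param metric `"ac"`, `"mi"`, or `"both"`.
#' @param seed Integer master seed, or `NULL`.
#' @param max_lag Number of positive lags for the mean autocorrelation.
#' @param smooth Apply a 3-point moving average before locating the argmax
#'   (the raw values are always kept).
#' @param independent Use an independent environment realisation per grid
#'   point instead of common random numbers.
#' @param n_bins Histogram resolution for the MI estimate.
#' @return An object of class `resonance_curve` with fields
#'   `sigma_n_sq_grid`, `mean_ac`, `mean_ac_smooth`, `mi_bits` (or NULL),
#'   `optimum_sigma_n_sq`, `optimum_value`, `degenerate`.
#' @examples
#' # genuinely sub-threshold signal: a real resonance peak
#' env <- env_config(mu_I = 0, sigma_I = 5, n_samples = 20000, seed = 1)
#' rc <- resonance_curve(env, sensor_params(I_theta = 30, mu_I = 0, sigma_I = 5),
#'                       noise_grid = seq(0, 30, 2)^2, seed = 2,
#'                       metric = "ac")
#' find_optimal_noise(rc)
#' @export
resonance_curve <- function(env, params, noise_grid = NULL,
                            metric = c("ac", "both", "mi"), seed = NULL,
                            max_lag = 50, smooth = TRUE, independent = FALSE,
                            n_bins = 64) {
  stopifnot(inherits(env, "env_config"), inherits(params, "sensor_params"))
  metric <- match.arg(metric)
  if (is.null(noise_grid))
    noise_grid <- noise_grid_default(if (env$sigma_I > 0) env$sigma_I
                                     else params$sigma_I)
  if (length(noise_grid) < 1L || any(diff(noise_grid) <= 0) ||
      any(noise_grid < 0))
    stopf("`noise_grid` must be a non-empty strictly increasing vector of non-negative variances")
  n_grid <- length(noise_grid)
  want_ac <- metric %in% c("ac", "both")
  want_mi <- metric %in% c("mi", "both")
  mean_ac <- if (want_ac) numeric(n_grid) else NULL
  mi_bits <- if (want_mi) numeric(n_grid) else NULL

  if (independent) {
    seeds <- derive_seeds(seed, 2L * n_grid)
    for (k in seq_len(n_grid)) {
      cfg <- env; cfg$seed <- seeds[[k]]
      s <- generate_ou_series(cfg)
      r <- respond(s, params, noise_model(noise_grid[k]),
                   seed = seeds[[n_grid + k]])
      if (want_ac) mean_ac[k] <- safe_mean_ac(r, max_lag)
      if (want_mi) mi_bits[k] <- mutual_information(s, r, n_bins)$value
    }
  } else {
    seeds <- derive_seeds(seed, 2L)
    cfg <- env; cfg$seed <- seeds[[1L]]
    s <- generate_ou_series(cfg)
    z <- with_seed(seeds[[2L]], stats::rnorm(env$n_samples))
    for (k in seq_len(n_grid)) {
      x <- s$values + sqrt(noise_grid[k]) * z
      rates <- rate_intensity(x, params)
      r <- firing_rate_series(rates, s$dt)
      if (want_ac) mean_ac[k] <- safe_mean_ac(r, max_lag)
      if (want_mi) mi_bits[k] <- mutual_information(s, r, n_bins)$value
    }
  }

  curve <- structure(
    list(sigma_n_sq_grid = noise_grid,
         mean_ac = mean_ac,
         mean_ac_smooth = if (want_ac && smooth) smooth3(mean_ac) else NULL,
         mi_bits = mi_bits,
         metric = metric, max_lag = max_lag, smooth = smooth,
         optimum_sigma_n_sq = NA_real_, optimum_value = NA_real_,
         degenerate = FALSE),
    class = "resonance_curve")
  opt <- find_optimal_noise(curve, quiet = TRUE)
  curve$optimum_sigma_n_sq <- as.numeric(opt)
  curve$optimum_value <- attr(opt, "value")
  curve$degenerate <- isTRUE(attr(opt, "degenerate"))
  curve
}

safe_mean_ac <- function(series, max_lag) {
  af <- autocorrelation_function(series, max_lag = max_lag)
  if (af$degenerate) 0 else mean(af$values[af$lags >= 1])
}

smooth3 <- function(v) {
  if (length(v) < 3L) return(v)
  out <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
  out[1L] <- v[1L]; out[length(v)] <- v[length(v)]
  out
}

#' Locate the optimal noise level on a resonance curve
#'
#' Argmax of the objective over the grid (the smoothed mean autocorrelation
#' if the curve was computed with `smooth = TRUE`); exact ties are broken
#' toward the smallest noise level. A fully degenerate curve — the output
#' autocorrelation is zero at every grid level, i.e. the signal never reaches
#' threshold even at the largest grid noise — returns the largest grid value
#' with a warning and attribute `degenerate = TRUE`.
#'
#' @param curve A [resonance_curve()].
#' @param metric Objective to maximise, `"ac"` (default) or `"mi"`.
#' @param quiet Suppress the degeneracy warning.
#' @return The optimal noise variance (dB^2), a grid member, with attributes
#'   `index`, `value` (raw objective at the optimum), and `degenerate`.
#' @export
find_optimal_noise <- function(curve, metric = c("ac", "mi"), quiet = FALSE) {
  stopifnot(inherits(curve, "resonance_curve"))
  metric <- match.arg(metric)
  if (metric == "ac" && is.null(curve$mean_ac))
    metric <- "mi"
  raw <- if (metric == "ac") curve$mean_ac else curve$mi_bits
  if (is.null(raw)) stopf("curve does not contain the requested metric")
  sel <- if (metric == "ac" && !is.null(curve$mean_ac_smooth))
    curve$mean_ac_smooth else raw
  if (all(raw == 0)) {
    if (!quiet)
      warning("degenerate resonance curve: objective is zero everywhere; ",
              "returning the largest grid noise level", call. = FALSE)
    k <- length(curve$sigma_n_sq_grid)
    return(structure(curve$sigma_n_sq_grid[k], index = k, value = raw[k],
                     degenerate = TRUE))
  }
  k <- which.max(sel) # first maximum: ties go to the smallest noise level
  structure(curve$sigma_n_sq_grid[k], index = k, value = raw[k],
            degenerate = FALSE)
}

#' @export
print.resonance_curve <- function(x, ...) {
  cat(sprintf("Resonance curve: %d noise levels, sigma_n in [0, %.1f] dB\n",
              length(x$sigma_n_sq_grid), sqrt(max(x$sigma_n_sq_grid))))
  if (x$degenerate) {
    cat("  degenerate: objective zero at every noise level\n")
  } else {
    cat(sprintf("  optimum: sigma_n^2 = %.2f dB^2 (sigma_n = %.2f dB), objective = %.4f\n",
                x$optimum_sigma_n_sq, sqrt(x$optimum_sigma_n_sq),
                x$optimum_value))
  }
  invisible(x)
}

#' @export
as.data.frame.resonance_curve <- function(x, ...) {
  df <- data.frame(sigma_n_sq = x$sigma_n_sq_grid)
  if (!is.null(x$mean_ac)) df$mean_ac <- x$mean_ac
  if (!is.null(x$mi_bits)) df$mi_bits <- x$mi_bits
  df
}

#' Feedback-controller settings for adaptive noise tuning
#'
#' @param n_probe_samples Environment samples per objective probe.
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence tolerance: relative change in sigma_n^2 (with an
#'   absolute floor near zero noise) that must not be exceeded over 10
#'   consecutive iterations.
#' @param step0 Initial step in noise-sd units (dB); default 0.3 sigma_I.
#' @param probe0 Initial finite-difference half-width in noise-sd units (dB);
#'   default 0.2 sigma_I.
#' @param explore_floor Objective level below which the controller treats the
#'   output as carrying no signal and explores upward instead of following
#'   the (then meaningless) gradient; default `2 / sqrt(n_probe_samples)`,
#'   the Monte-Carlo noise scale of the mean-autocorrelation estimate.
#' @return A list of class `feedback_controller`.
#' @export
feedback_controller <- function(n_probe_samples = 1e5, max_iter = 60,
                                tol = 0.01, step0 = NULL, probe0 = NULL,
                                explore_floor = NULL) {
  check_number(n_probe_samples, "n_probe_samples", lower = 100,
               integerish = TRUE)
  check_number(max_iter, "max_iter", lower = 1, integerish = TRUE)
  check_number(tol, "tol", lower = .Machine$double.eps)
  check_number(step0, "step0", lower = 0, allow_null = TRUE)
  check_number(probe0, "probe0", lower = 0, allow_null = TRUE)
  check_number(explore_floor, "explore_floor", lower = 0, allow_null = TRUE)
  structure(list(n_probe_samples = as.integer(n_probe_samples),
                 max_iter = as.integer(max_iter), tol = tol,
                 step0 = step0, probe0 = probe0,
                 explore_floor = explore_floor),
            class = "feedback_controller")
}

#' Closed-loop adaptive tuning of the injected-noise level
#'
#' A plausible realisation of the feedback loop in which an information
#' detector (mean output autocorrelation) controls a noise generator:
#' stochastic hill climbing on the noise standard deviation. Each iteration
#' estimates the objective at sigma_n +/- a probe half-width on one fresh
#' environment realisation (the same realisation and the same noise draws,
#' scaled, for both probes, so the finite difference is not swamped by
#' re-sampling error) and moves sigma_n by a decaying step in the uphill
#' direction, projected at 0. The loop terminates on `max_iter` or when the
#' relative change in sigma_n^2 stays below `tol` for 10 iterations.
#'
#' The model presumes only that the noise level settles where the output
#' autocorrelation is maximal; no dynamics or timescale is prescribed, so the
#' controller is a documented implementation choice, validated against the
#' grid-search optimum of [resonance_curve()].
#'
#' @param env An [env_config()].
#' @param params A [sensor_params()].
#' @param controller A [feedback_controller()].
#' @param seed Integer master seed, or `NULL`.
#' @param sigma_n_sq_init Starting noise variance, dB^2.
#' @param max_lag Lags for the mean-autocorrelation objective.
#' @return An object of class `feedback_trajectory`: data frame `path`
#'   (iteration, sigma_n_sq, mean_ac), `terminal_sigma_n_sq`, `converged`.
#' @export
run_feedback_loop <- function(env, params, controller = feedback_controller(),
                              seed = NULL, sigma_n_sq_init = 0, max_lag = 50) {
  stopifnot(inherits(env, "env_config"), inherits(params, "sensor_params"),
            inherits(controller, "feedback_controller"))
  check_number(sigma_n_sq_init, "sigma_n_sq_init", lower = 0)
  sig_ref <- if (env$sigma_I > 0) env$sigma_I else params$sigma_I
  step0 <- if (is.null(controller$step0)) 0.3 * sig_ref else controller$step0
  probe0 <- if (is.null(controller$probe0)) 0.2 * sig_ref else controller$probe0
  explore_floor <- if (is.null(controller$explore_floor))
    2 / sqrt(controller$n_probe_samples) else controller$explore_floor
  floor_sq <- (0.1 * sig_ref)^2 # absolute tolerance floor near zero noise

  seeds <- derive_seeds(seed, controller$max_iter)
  sn <- sqrt(sigma_n_sq_init)
  path <- data.frame(iteration = integer(0), sigma_n_sq = numeric(0),
                     mean_ac = numeric(0))
  still <- 0L; converged <- FALSE
  for (k in seq_len(controller$max_iter)) {
    ck <- probe0 / k^0.101
    ak <- step0 / k^0.602
    pr <- with_seed(seeds[[k]], {
      cfg <- env; cfg$seed <- NULL; cfg$n_samples <- controller$n_probe_samples
      s <- generate_ou_series(cfg)
      list(I = s$values, dt = s$dt, z = stats::rnorm(cfg$n_samples))
    })
    probe <- function(sd_n) {
      sd_n <- max(sd_n, 0)
      safe_mean_ac(firing_rate_series(
        rate_intensity(pr$I + sd_n * pr$z, params), pr$dt), max_lag)
    }
    j_hi <- probe(sn + ck)
    j_lo <- probe(max(sn - ck, 0))
    # Below the Monte-Carlo noise floor the output carries no measurable
    # signal and the local gradient is meaningless; the only move that can
    # help is more noise, so the controller explores upward at full step —
    # unless the downhill direction is clearly resolved (supra-threshold
    # regime, where the objective drops from a well-measured value at 0).
    if (max(j_hi, j_lo) < explore_floor && j_hi >= j_lo) {
      sn_new <- sn + step0
    } else {
      sn_new <- max(sn + ak * sign(j_hi - j_lo), 0)
    }
    rel <- abs(sn_new^2 - sn^2) / max(sn^2, floor_sq)
    still <- if (rel < controller$tol) still + 1L else 0L
    sn <- sn_new
    path <- rbind(path, data.frame(iteration = k, sigma_n_sq = sn^2,
                                   mean_ac = (j_hi + j_lo) / 2))
    if (still >= 10L) { converged <- TRUE; break }
  }
  structure(list(path = path, terminal_sigma_n_sq = sn^2,
                 converged = converged),
            class = "feedback_trajectory")
}

#' @export
print.feedback_trajectory <- function(x, ...) {
  cat(sprintf(
    "Feedback trajectory: %d iterations, terminal sigma_n^2 = %.2f dB^2, %s\n",
    nrow(x$path), x$terminal_sigma_n_sq,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}
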