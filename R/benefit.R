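#' Psychometric function of the noisy threshold sensor
#'
#' Detection probability versus probe intensity, estimated by Monte-Carlo. A
#' trial presents a constant probe intensity I for `window_m` consecutive
#' noise samples and counts as a detection iff any sample of the summed input
#' crosses the threshold, I + n >= I_theta (equivalently, the response
#' exceeds the spontaneous rate at least once in the window). The behavioural
#' hearing threshold is the 50%-detection point, interpolated linearly.
#'
#' All probe intensities share the same simulated noise windows, so the
#' estimated curve is non-decreasing in I by construction and the 50% point
#' is the empirical median of (I_theta - max window noise).
#'
#' With zero noise the curve is a step at the threshold and `threshold_50`
#' equals `I_theta` exactly. A symmetric single noise draw (`window_m = 1`)
#' gives p(I) = Phi((I - I_theta)/sigma_n) and leaves the 50% point at the
#' threshold; only a multi-sample window moves it, by
#' sigma_n * qnorm(0.5^(1/m)) dB leftward — the stochastic-resonance gain in
#' detectability.
#'
#' @param params A [sensor_params()].
#' @param sigma_n_sq Injected-noise variance, dB^2.
#' @param probe_grid Increasing vector of probe intensities, dB SPL. Must
#'   span the 50% crossing.
#' @param window_m Detection-window length in noise samples (>= 1).
#' @param n_trials Monte-Carlo trials per probe (>= 100).
#' @param seed Integer RNG seed, or `NULL`.
#' @return An object of class `psychometric_curve`: `probe_intensities`,
#'   `detection_prob`, `threshold_50`.
#' @examples
#' pc <- psychometric_curve(sensor_params(I_theta = 20), sigma_n_sq = 16,
#'                          probe_grid = seq(0, 30, 0.5), seed = 1)
#' pc$threshold_50
#' @export
psychometric_curve <- function(params, sigma_n_sq, probe_grid, window_m = 10,
                               n_trials = 1000, seed = NULL) {
  stopifnot(inherits(params, "sensor_params"))
  check_number(sigma_n_sq, "sigma_n_sq", lower = 0)
  check_number(window_m, "window_m", lower = 1, integerish = TRUE)
  check_number(n_trials, "n_trials", lower = 100, integerish = TRUE)
  if (length(probe_grid) < 2L || any(diff(probe_grid) <= 0))
    stopf("`probe_grid` must be an increasing vector of intensities")
  theta <- params$I_theta
  if (sigma_n_sq == 0) {
    p <- as.numeric(probe_grid >= theta)
  } else {
    max_noise <- with_seed(seed, {
      draws <- matrix(stats::rnorm(n_trials * window_m, 0, sqrt(sigma_n_sq)),
                      nrow = n_trials)
      apply(draws, 1L, max)
    })
    # detection iff probe + max window noise >= threshold
    p <- vapply(probe_grid, function(I) mean(max_noise >= theta - I),
                numeric(1))
  }
  t50 <- threshold_from_curve(probe_grid, p)
  structure(list(probe_intensities = probe_grid, detection_prob = p,
                 threshold_50 = t50, window_m = window_m,
                 sigma_n_sq = sigma_n_sq),
            class = "psychometric_curve")
}

threshold_from_curve <- function(probe, p) {
  if (p[1L] >= 0.5 || p[length(p)] < 0.5)
    stopf(paste0("probe grid [%g, %g] does not span the 50%% crossing ",
                 "(detection probability covers [%g, %g]); extend the grid"),
          min(probe), max(probe), min(p), max(p))
  i <- which(p >= 0.5)[1L]
  if (p[i] == p[i - 1L]) return(probe[i])
  if (p[i - 1L] == 0 && p[i] == 1) return(probe[i]) # deterministic step
  probe[i - 1L] + (0.5 - p[i - 1L]) / (p[i] - p[i - 1L]) *
    (probe[i] - probe[i - 1L])
}

#' @export
print.psychometric_curve <- function(x, ...) {
  cat(sprintf(
    "Psychometric curve: %d probes, sigma_n^2 = %g dB^2, window m = %d\n",
    length(x$probe_intensities), x$sigma_n_sq, x$window_m))
  cat(sprintf("  50%%-detection threshold: %.2f dB SPL\n", x$threshold_50))
  invisible(x)
}

#' @export
as.data.frame.psychometric_curve <- function(x, ...) {
  data.frame(probe_db = x$probe_intensities, detection_prob = x$detection_prob)
}

#' Threshold benefit of optimal noise, by the psychometric estimator
#'
#' Elevates the sensor threshold by `hearing_loss` dB, finds the noise level
#' maximising the mean output autocorrelation on the acoustic environment
#' (grid search via [resonance_curve()]), and reports the shift of the
#' 50%-detection point: threshold without noise minus threshold at the
#' optimal noise, in dB.
#'
#' @param hearing_loss Threshold elevation, dB (>= 0).
#' @param env An [env_config()]; the environment the noise is tuned on.
#' @param base_params Baseline [sensor_params()] (healthy threshold).
#' @param window_m Detection-window length for the psychometric trials.
#' @param n_trials Monte-Carlo trials per probe.
#' @param probe_step Probe spacing, dB.
#' @param noise_grid Optional noise grid for the resonance search.
#' @param seed Integer master seed, or `NULL`.
#' @param max_lag Lags for the mean-autocorrelation objective.
#' @return An object of class `detection_benefit`: `benefit_db`,
#'   `threshold_no_sr`, `threshold_with_sr`, `sigma_n_opt_sq`, and the two
#'   psychometric curves.
#' @export
benefit_by_detection <- function(hearing_loss, env,
                                 base_params = sensor_params(),
                                 window_m = 10, n_trials = 2000,
                                 probe_step = 0.25, noise_grid = NULL,
                                 seed = NULL, max_lag = 50) {
  check_number(hearing_loss, "hearing_loss", lower = 0)
  params <- base_params
  params$I_theta <- base_params$I_theta + hearing_loss
  seeds <- derive_seeds(seed, 3L)
  rc <- resonance_curve(env, params, noise_grid = noise_grid,
                        metric = "ac", seed = seeds[[1L]], max_lag = max_lag)
  if (rc$degenerate)
    warning("resonance curve is degenerate; benefit computed at the largest ",
            "grid noise level", call. = FALSE)
  sn_opt_sq <- rc$optimum_sigma_n_sq
  sd_opt <- sqrt(sn_opt_sq)
  probes <- seq(params$I_theta - 4 * sd_opt - 2,
                params$I_theta + sd_opt + 2, by = probe_step)
  pc0 <- psychometric_curve(params, 0, probes, window_m, n_trials, seeds[[2L]])
  pc1 <- psychometric_curve(params, sn_opt_sq, probes, window_m, n_trials,
                            seeds[[3L]])
  structure(list(benefit_db = pc0$threshold_50 - pc1$threshold_50,
                 threshold_no_sr = pc0$threshold_50,
                 threshold_with_sr = pc1$threshold_50,
                 sigma_n_opt_sq = sn_opt_sq,
                 curve_no_sr = pc0, curve_with_sr = pc1,
                 hearing_loss = hearing_loss),
            class = "detection_benefit")
}

#' @export
print.detection_benefit <- function(x, ...) {
  cat(sprintf("Detection-threshold benefit at %g dB hearing loss\n",
              x$hearing_loss))
  cat(sprintf(
    "  threshold %.2f dB (no noise) -> %.2f dB (sigma_n^2 = %.1f dB^2): benefit %.2f dB\n",
    x$threshold_no_sr, x$threshold_with_sr, x$sigma_n_opt_sq, x$benefit_db))
  invisible(x)
}

#' Mean output autocorrelation versus hearing threshold, with and without SR
#'
#' Sweeps the sensor threshold over `thresholds`, and for each threshold
#' evaluates the mean output autocorrelation of the response to the
#' environment at zero noise and at the autocorrelation-optimal noise level
#' located by grid search. One environment realisation and one scaled noise
#' vector are shared across all thresholds and grid levels (common random
#' numbers), so the no-SR curve decreases smoothly in the threshold and the
#' with-SR curve is, by construction of the argmax, pointwise >= the no-SR
#' curve.
#'
#' @param env An [env_config()].
#' @param thresholds Increasing vector of hearing thresholds, dB SPL.
#' @param base_params Baseline [sensor_params()]; only its rates and adapted
#'   distribution are used, the threshold field is swept.
#' @param noise_grid Optional noise-variance grid (dB^2).
#' @param seed Integer master seed, or `NULL`.
#' @param max_lag Lags for the mean autocorrelation.
#' @param smooth Smooth each resonance curve before locating its argmax.
#' @return An object of class `ac_threshold_curve` wrapping a data frame
#'   with columns `threshold`, `mean_ac_no_sr`, `mean_ac_with_sr`,
#'   `sigma_n_opt_sq`.
#' @export
ac_threshold_curve <- function(env, thresholds = seq(0, 60, by = 2),
                               base_params = sensor_params(),
                               noise_grid = NULL, seed = NULL, max_lag = 50,
                               smooth = TRUE) {
  stopifnot(inherits(env, "env_config"))
  if (length(thresholds) < 2L || any(diff(thresholds) <= 0))
    stopf("`thresholds` must be an increasing vector")
  if (is.null(noise_grid))
    noise_grid <- noise_grid_default(if (env$sigma_I > 0) env$sigma_I
                                     else base_params$sigma_I)
  seeds <- derive_seeds(seed, 2L)
  cfg <- env; cfg$seed <- seeds[[1L]]
  s <- generate_ou_series(cfg)
  z <- with_seed(seeds[[2L]], stats::rnorm(env$n_samples))
  sd_grid <- sqrt(noise_grid)

  out <- lapply(thresholds, function(th) {
    params <- base_params; params$I_theta <- th
    ac <- vapply(sd_grid, function(sn)
      safe_mean_ac(firing_rate_series(
        rate_intensity(s$values + sn * z, params), s$dt), max_lag),
      numeric(1))
    sel <- if (smooth) smooth3(ac) else ac
    k <- if (all(ac == 0)) length(ac) else which.max(sel)
    c(no_sr = ac[1L], with_sr = ac[k], opt = noise_grid[k])
  })
  m <- do.call(rbind, out)
  structure(list(table = data.frame(threshold = thresholds,
                                    mean_ac_no_sr = m[, "no_sr"],
                                    mean_ac_with_sr = m[, "with_sr"],
                                    sigma_n_opt_sq = m[, "opt"]),
                 max_lag = max_lag),
            class = "ac_threshold_curve")
}

#' @export
print.ac_threshold_curve <- function(x, ...) {
  t <- x$table
  cat(sprintf("AC-vs-threshold curve: thresholds %g..%g dB (%d points)\n",
              min(t$threshold), max(t$threshold), nrow(t)))
  cat(sprintf("  mean AC (no SR) %.4f -> %.4f across the sweep\n",
              t$mean_ac_no_sr[1L], t$mean_ac_no_sr[nrow(t)]))
  invisible(x)
}

#' @export
as.data.frame.ac_threshold_curve <- function(x, ...) x$table

#' Threshold benefit of optimal noise, by iso-autocorrelation matching
#'
#' Reads the benefit off the AC-versus-threshold curves: the with-SR mean
#' autocorrelation at threshold `hearing_loss` is matched on the monotone
#' no-SR curve, giving the lower threshold I' that would transmit the same
#' information without noise; the benefit is `hearing_loss` - I' in dB
#' (the horizontal iso-AC arrow between the two curves).
#'
#' @param hearing_loss Threshold elevation, dB; must lie within the curve's
#'   threshold range.
#' @param curve An [ac_threshold_curve()].
#' @return Benefit in dB (a single number).
#' @export
benefit_by_ac <- function(hearing_loss, curve) {
  stopifnot(inherits(curve, "ac_threshold_curve"))
  t <- curve$table
  check_number(hearing_loss, "hearing_loss",
               lower = min(t$threshold), upper = max(t$threshold))
  target <- stats::approx(t$threshold, t$mean_ac_with_sr,
                          xout = hearing_loss)$y
  # Invert on the strictly decreasing envelope of the no-SR curve: once the
  # curve flattens (e.g. at zero for fully sub-threshold thresholds) the
  # AC -> threshold mapping is no longer one-to-one and those points carry
  # no iso-AC information.
  keep <- logical(nrow(t))
  keep[1L] <- TRUE
  last <- t$mean_ac_no_sr[1L]
  for (i in seq_len(nrow(t))[-1L]) {
    if (t$mean_ac_no_sr[i] < last - 1e-12) {
      keep[i] <- TRUE
      last <- t$mean_ac_no_sr[i]
    }
  }
  no_sr <- t$mean_ac_no_sr[keep]
  thr <- t$threshold[keep]
  if (target > max(no_sr) + 1e-12 || target < min(no_sr) - 1e-12)
    stopf(paste0("target autocorrelation %.4f is outside the no-SR curve ",
                 "range [%.4f, %.4f]; extend the threshold grid"),
          target, min(no_sr), max(no_sr))
  matched <- stats::approx(rev(no_sr), rev(thr), xout = target,
                           ties = "ordered")$y
  hearing_loss - matched
}

#' Stochastic-resonance threshold benefit by both estimators
#'
#' Convenience wrapper computing, for one or more hearing-loss levels, the
#' optimal noise level on the environment and the benefit by the
#' psychometric (50%-detection shift) and iso-autocorrelation estimators.
#'
#' @param hearing_loss Vector of threshold elevations, dB.
#' @param env An [env_config()].
#' @param base_params Baseline [sensor_params()].
#' @param curve Optional precomputed [ac_threshold_curve()]; computed over
#'   0..60 dB if missing.
#' @param window_m,n_trials Psychometric settings, see
#'   [benefit_by_detection()].
#' @param seed Integer master seed, or `NULL`.
#' @param ... Passed on to [benefit_by_detection()].
#' @return Data frame with columns `hearing_loss`, `benefit_ac`,
#'   `benefit_detection`, `sigma_n_opt_sq`.
#' @export
sr_benefit <- function(hearing_loss, env, base_params = sensor_params(),
                       curve = NULL, window_m = 10, n_trials = 2000,
                       seed = NULL, ...) {
  seeds <- derive_seeds(seed, length(hearing_loss) + 1L)
  if (is.null(curve))
    curve <- ac_threshold_curve(env, base_params = base_params,
                                seed = seeds[[length(hearing_loss) + 1L]])
  rows <- lapply(seq_along(hearing_loss), function(i) {
    loss <- hearing_loss[i]
    det <- benefit_by_detection(loss, env, base_params, window_m = window_m,
                                n_trials = n_trials, seed = seeds[[i]], ...)
    data.frame(hearing_loss = loss,
               benefit_ac = benefit_by_ac(loss, curve),
               benefit_detection = det$benefit_db,
               sigma_n_opt_sq = det$sigma_n_opt_sq)
  })
  do.call(rbind, rows)
}
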