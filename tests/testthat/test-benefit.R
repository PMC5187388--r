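test_that("zero-noise psychometric function is a step at the threshold", {
  pc <- psychometric_curve(sensor_params(I_theta = 20), 0,
                           probe_grid = seq(10, 30, 0.5))
  expect_equal(pc$threshold_50, 20)
  expect_equal(pc$detection_prob, as.numeric(pc$probe_intensities >= 20))
})

test_that("single-draw noise gives the Gaussian psychometric with unmoved threshold", {
  # oracle: p(I) = Phi((I - theta)/sigma_n); the 50% point stays at theta
  theta <- 20; sn <- 5
  pc <- psychometric_curve(sensor_params(I_theta = theta), sn^2,
                           probe_grid = seq(0, 40, 0.5), window_m = 1,
                           n_trials = 4000, seed = 31)
  oracle <- pnorm((pc$probe_intensities - theta) / sn)
  expect_lt(max(abs(pc$detection_prob - oracle)), 0.03)
  expect_lt(abs(pc$threshold_50 - theta), 0.3)
})

test_that("multi-sample windows shift the 50% point below threshold", {
  # oracle: p(I) = 1 - Phi((theta - I)/sigma_n)^m, so the threshold moves to
  # theta - sigma_n * qnorm(0.5^(1/m))
  theta <- 40; sn <- 4; m <- 10
  pc <- psychometric_curve(sensor_params(I_theta = theta), sn^2,
                           probe_grid = seq(20, 50, 0.25), window_m = m,
                           n_trials = 4000, seed = 13)
  oracle_p <- 1 - pnorm((theta - pc$probe_intensities) / sn)^m
  expect_lt(max(abs(pc$detection_prob - oracle_p)), 0.03)
  oracle_t50 <- theta - sn * qnorm(0.5^(1 / m))
  expect_lt(abs(pc$threshold_50 - oracle_t50), 0.4)
  expect_lt(pc$threshold_50, theta)
  # detection probability is non-decreasing in the probe intensity
  expect_true(all(diff(pc$detection_prob) >= 0))
})

test_that("psychometric curve demands a grid spanning the 50% point", {
  expect_error(
    psychometric_curve(sensor_params(I_theta = 20), 4,
                       probe_grid = seq(30, 40, 1), seed = 1),
    "span")
  expect_error(
    psychometric_curve(sensor_params(I_theta = 20), 4,
                       probe_grid = seq(-10, 0, 1), seed = 1),
    "span")
})

test_that("iso-AC benefit interpolates hand-built curves correctly", {
  # no-SR curve: AC = 0.2 - 0.002 * threshold; with-SR adds 0.004,
  # so every loss maps 2 dB down the no-SR curve
  thr <- seq(0, 60, 10)
  curve <- structure(list(table = data.frame(
    threshold = thr,
    mean_ac_no_sr = 0.2 - 0.002 * thr,
    mean_ac_with_sr = 0.2 - 0.002 * thr + 0.004,
    sigma_n_opt_sq = 9), max_lag = 50), class = "ac_threshold_curve")
  expect_equal(benefit_by_ac(30, curve), 2, tolerance = 1e-9)
  # identical curves: zero benefit
  curve$table$mean_ac_with_sr <- curve$table$mean_ac_no_sr
  expect_equal(benefit_by_ac(30, curve), 0, tolerance = 1e-9)
  # target outside the no-SR range
  curve$table$mean_ac_with_sr <- curve$table$mean_ac_no_sr + 0.1
  expect_error(benefit_by_ac(10, curve), "extend the threshold grid")
})

test_that("AC-vs-threshold sweep is monotone and SR-dominated", {
  env <- std_env(n = 3e4, seed = 51)
  atc <- ac_threshold_curve(env, thresholds = seq(0, 60, 10), seed = 52)
  t <- atc$table
  expect_true(all(diff(t$mean_ac_no_sr) < 0))
  expect_true(all(t$mean_ac_with_sr >= t$mean_ac_no_sr))
  expect_true(all(diff(t$sigma_n_opt_sq) >= 0))
})

test_that("iso-AC benefit is positive in the sub-threshold regime and robust to lag count", {
  env <- weak_env()
  benefits <- sapply(c(20, 50, 100), function(N) {
    atc <- ac_threshold_curve(env, thresholds = seq(10, 34, 2),
                              base_params = weak_params(0),
                              noise_grid = seq(0, 25, 1)^2, seed = 7,
                              max_lag = N)
    c(benefit_by_ac(26, atc), benefit_by_ac(30, atc))
  })
  expect_true(all(benefits > 1))
  # headline numbers barely move with the number of evaluated lags
  expect_lt(max(benefits[1, ]) - min(benefits[1, ]), 0.5)
  expect_lt(max(benefits[2, ]) - min(benefits[2, ]), 0.5)
})

test_that("detection benefit vanishes without threshold elevation", {
  env <- std_env(n = 3e4, seed = 61)
  b <- benefit_by_detection(0, env, seed = 62, n_trials = 500)
  expect_lt(abs(b$benefit_db), 0.5)
  expect_equal(b$threshold_no_sr, 0, tolerance = 1e-9)
})
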