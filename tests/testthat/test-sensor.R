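test_that("spontaneous probability is the sub-threshold Gaussian mass", {
  # oracle: numerical integration of the intensity density below threshold
  by_integration <- stats::integrate(gaussian_intensity_pdf, -Inf, 0)$value
  expect_equal(spontaneous_probability(sensor_params()), by_integration,
               tolerance = 1e-6)
  expect_lt(abs(spontaneous_probability(sensor_params()) - 0.0548), 1e-4)
  expect_equal(spontaneous_probability(sensor_params(I_theta = 40)), 0.5)
  expect_equal(spontaneous_probability(sensor_params(I_theta = -1e4)), 0)
})

test_that("rate-intensity function hits its anchor values", {
  p <- sensor_params()
  expect_equal(rate_intensity(-10, p), 50)
  expect_equal(rate_intensity(1e4, p), 250, tolerance = 1e-9)
  # oracle: independent evaluation through the Gaussian CDF
  psp <- pnorm(-1.6)
  oracle_40 <- 50 + 200 * (pnorm(0) - psp) / (1 - psp)
  expect_equal(rate_intensity(40, p), oracle_40, tolerance = 1e-12)
  expect_lt(abs(rate_intensity(40, p) - 144.2), 0.05)
  # continuity at the threshold
  expect_equal(rate_intensity(p$I_theta, p), 50)
  expect_equal(rate_intensity(p$I_theta + 1e-9, p), 50, tolerance = 1e-6)
})

test_that("rate-intensity is monotone, bounded, and ordered in threshold", {
  I <- seq(-60, 160, by = 0.5)
  for (theta in c(-10, 0, 20, 40, 60)) {
    f <- rate_intensity(I, sensor_params(I_theta = theta))
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f >= 50 - 1e-12 & f <= 250 + 1e-12))
  }
  # raising the threshold weakly decreases the rate pointwise
  f20 <- rate_intensity(I, sensor_params(I_theta = 20))
  f40 <- rate_intensity(I, sensor_params(I_theta = 40))
  expect_true(all(f40 <= f20 + 1e-12))
  # parameter validation
  expect_error(sensor_params(f_sp = 100, f_max = 80), "f_max")
  expect_error(sensor_params(f_sp = -1), "f_sp")
})

test_that("respond reduces to the deterministic map at zero noise", {
  s <- generate_ou_series(env_config(n_samples = 2000, seed = 3))
  p <- sensor_params(I_theta = 20)
  r0 <- respond(s, p, noise_model(0))
  expect_equal(r0$values, rate_intensity(s$values, p))
  r1 <- respond(s, p, noise_model(30), seed = 9)
  expect_identical(r1$values, respond(s, p, 30, seed = 9)$values)
  expect_true(all(r1$values >= 50 & r1$values <= 250))
})

test_that("noise-induced threshold crossings match the Gaussian exceedance", {
  # constant input delta below threshold: crossing fraction 1 - Phi(delta/s)
  delta <- 2; sn <- 5
  s <- intensity_series(rep(20 - delta, 2e4), 0.1)
  r <- respond(s, sensor_params(I_theta = 20), noise_model(sn^2), seed = 77)
  expect_lt(abs(mean(r$values > 50) - (1 - pnorm(delta / sn))), 0.02)
})

test_that("noise makes the expected response increase smoothly through threshold", {
  p <- sensor_params(I_theta = 20)
  means <- sapply(seq(10, 30, 2.5), function(I) {
    mean(respond(intensity_series(rep(I, 4000), 0.1), p, noise_model(25),
                 seed = round(I * 10))$values)
  })
  expect_true(all(diff(means) > 0))
})

test_that("a sub-threshold signal is transmitted only with noise", {
  # fully sub-threshold environment: zero noise -> constant output, AC zero;
  # moderate noise -> output carries the input's temporal correlation
  env <- weak_env(n = 5e4)
  p <- weak_params(20)
  s <- generate_ou_series(env)
  silent <- respond(s, p, noise_model(0))
  expect_equal(sd(silent$values), 0)
  expect_true(autocorrelation_function(silent, 20)$degenerate)
  expect_equal(mean_autocorrelation(silent, 20), 0)

  noisy <- respond(s, p, noise_model(81), seed = 5)
  expect_gt(mean_autocorrelation(noisy, 20), 0.005)
})
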