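make_curve <- function(grid_sq, ac) {
  structure(list(sigma_n_sq_grid = grid_sq, mean_ac = ac,
                 mean_ac_smooth = NULL, mi_bits = NULL, metric = "ac",
                 max_lag = 50, smooth = FALSE,
                 optimum_sigma_n_sq = NA_real_, optimum_value = NA_real_,
                 degenerate = FALSE),
            class = "resonance_curve")
}

test_that("find_optimal_noise locates argmax with smallest-noise tie-break", {
  g <- (0:10)^2
  expect_equal(as.numeric(find_optimal_noise(make_curve(g, seq(1, 0, -0.1)))), 0)
  peaked <- c(0, 0.1, 0.4, 0.9, 0.6, 0.3, 0.2, 0.1, 0.05, 0.02, 0.01)
  expect_equal(as.numeric(find_optimal_noise(make_curve(g, peaked))), 9)
  tied <- c(0, 0.2, 0.5, 0.5, 0.3, 0.1, 0, 0, 0, 0, 0)
  expect_equal(as.numeric(find_optimal_noise(make_curve(g, tied))), 4)
  # degenerate all-zero curve: largest grid value, flagged, with a warning
  expect_warning(d <- find_optimal_noise(make_curve(g, rep(0, 11))),
                 "degenerate")
  expect_equal(as.numeric(d), 100)
  expect_true(attr(d, "degenerate"))
})

test_that("noise grid covers 0 to three environment sd in equal sd steps", {
  g <- noise_grid_default(25)
  expect_length(g, 60)
  expect_equal(g[1], 0)
  expect_equal(max(g), 75^2)
  expect_true(all(diff(sqrt(g)) - sqrt(g)[2] < 1e-9))
  expect_error(resonance_curve(std_env(1000), sensor_params(),
                               noise_grid = c(4, 1)), "increasing")
})

test_that("a fully supra-threshold signal is best transmitted without noise", {
  # threshold six sd below the environment mean: noise can only degrade
  env <- std_env(n = 2e4, seed = 41)
  rc <- resonance_curve(env, sensor_params(I_theta = 40 - 6 * 25), seed = 42)
  expect_equal(rc$optimum_sigma_n_sq, 0)
  expect_false(rc$degenerate)
  # and the objective declines with growing noise overall
  expect_lt(rc$mean_ac[30], rc$mean_ac[1])
})

test_that("resonance curves are reproducible under a fixed seed", {
  env <- weak_env(n = 2e4)
  a <- resonance_curve(env, weak_params(20), noise_grid = seq(0, 20, 2)^2,
                       seed = 5)
  b <- resonance_curve(env, weak_params(20), noise_grid = seq(0, 20, 2)^2,
                       seed = 5)
  expect_identical(a$mean_ac, b$mean_ac)
})

test_that("sub-threshold signals show genuine stochastic resonance", {
  env <- weak_env()
  grid <- seq(0, 30, 0.5)^2
  rc20 <- resonance_curve(env, weak_params(20), noise_grid = grid, seed = 60,
                          max_lag = 20)
  # zero transmission without noise, interior optimum, decline after it
  expect_lt(abs(rc20$mean_ac[1]), 1e-3)
  expect_gt(rc20$optimum_sigma_n_sq, 0)
  expect_lt(rc20$optimum_sigma_n_sq, max(grid))
  expect_gt(rc20$optimum_value, 0.015)
  expect_lt(rc20$mean_ac[length(grid)], 0.8 * rc20$optimum_value)

  # deeper threshold: more noise needed, weaker peak, later onset
  rc25 <- resonance_curve(env, weak_params(25), noise_grid = grid, seed = 60,
                          max_lag = 20)
  expect_gt(rc25$optimum_sigma_n_sq, rc20$optimum_sigma_n_sq)
  expect_lt(rc25$optimum_value, rc20$optimum_value)
  onset <- function(rc) which(rc$mean_ac > 0.002)[1]
  expect_gt(onset(rc25), onset(rc20))
})

test_that("feedback loop reaches the grid-search optimum from zero noise", {
  env <- weak_env()
  p <- weak_params(20)
  rc <- resonance_curve(env, p, noise_grid = seq(0, 25, 0.5)^2, seed = 52,
                        max_lag = 20)
  tr <- run_feedback_loop(env, p, feedback_controller(max_iter = 80),
                          seed = 2, max_lag = 20)
  expect_lt(abs(tr$terminal_sigma_n_sq - rc$optimum_sigma_n_sq),
            0.2 * rc$optimum_sigma_n_sq)
  # terminal objective is near-peak on the measured curve
  j_term <- approx(rc$sigma_n_sq_grid, rc$mean_ac,
                   xout = tr$terminal_sigma_n_sq, rule = 2)$y
  expect_gt(j_term, 0.85 * rc$optimum_value)
})

test_that("feedback loop stays at the optimum when started there", {
  env <- weak_env()
  p <- weak_params(20)
  rc <- resonance_curve(env, p, noise_grid = seq(0, 25, 0.5)^2, seed = 52,
                        max_lag = 20)
  tr <- run_feedback_loop(env, p, feedback_controller(max_iter = 40),
                          seed = 9, sigma_n_sq_init = rc$optimum_sigma_n_sq,
                          max_lag = 20)
  j_term <- approx(rc$sigma_n_sq_grid, rc$mean_ac,
                   xout = tr$terminal_sigma_n_sq, rule = 2)$y
  expect_gt(j_term, 0.85 * rc$optimum_value)
})

test_that("feedback loop drives noise to zero for supra-threshold signals", {
  env <- std_env(n = 3e4, seed = 44)
  tr <- run_feedback_loop(env, sensor_params(I_theta = -60),
                          feedback_controller(n_probe_samples = 2e4,
                                              max_iter = 30), seed = 4)
  expect_equal(tr$terminal_sigma_n_sq, 0)
  expect_true(tr$converged)
})
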