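# Shared fixtures. The "standard" environment is N(40 dB, 25 dB sd); the
# "weak" environment is a quiet variant (N(0, 5)) whose intensities sit far
# below the elevated thresholds used in the resonance tests, i.e. the regime
# in which added noise can genuinely carry signal across the threshold.

std_env <- function(n = 5e4, seed = 101) {
  env_config(n_samples = n, seed = seed)
}

weak_env <- function(n = 1e5, seed = 12) {
  env_config(mu_I = 0, sigma_I = 5, n_samples = n, seed = seed)
}

weak_params <- function(theta) {
  sensor_params(I_theta = theta, mu_I = 0, sigma_I = 5)
}
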