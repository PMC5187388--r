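# adaptsr

Adaptive stochastic resonance in a single-channel model of the auditory
periphery: can optimally tuned internal noise restore hearing thresholds
after cochlear damage?

## The scientific problem

Weak signals that fall below a sensory threshold are invisible to the
detector behind it — unless noise is added to the input, in which case the
signal occasionally rides a noise fluctuation across the threshold and is
transmitted. There is an optimal, non-zero noise level for this effect
(stochastic resonance, SR), and a system that *continuously tunes* its
internal noise to keep an information objective maximal performs *adaptive*
SR. In the auditory system, such noise tuning has been proposed as a
compensation mechanism after hearing loss, with permanently raised internal
noise as a side effect — a candidate explanation for tinnitus-related
neuronal hyperactivity.

`adaptsr` implements the full simulation chain for one frequency channel:

* **Acoustic environment** — sound intensity levels `I(t)` (dB SPL) from an
  Ornstein–Uhlenbeck process with stationary law N(μ_I = 40, σ_I² = 25²)
  and autocorrelation `exp(−τ)`; an i.i.d. control with the same marginal.
* **Sensor** (inner-hair-cell synapse / auditory nerve) — infomax
  rate-intensity function: spontaneous rate f_sp = 50 Hz below the hearing
  threshold I_θ, rising with the adapted intensity CDF to f_max = 250 Hz,

      f(I) = f_sp + (f_max − f_sp) · [Φ((I−μ_I)/σ_I) − P_sp] / (1 − P_sp),  I ≥ I_θ,

  with P_sp = Φ((I_θ−μ_I)/σ_I). Hearing loss = threshold elevation, nothing
  else. Internal noise n ~ N(0, σ_n²) is added per sample before
  thresholding: `f(I + n)`.
* **Information metrics** — lag-averaged output autocorrelation (Pearson
  normalised) and a histogram mutual-information estimate.
* **Adaptive SR** — resonance curves (objective vs. σ_n²), grid-search
  optimum σ²_{n,opt}(AC), and a closed-loop hill-climbing noise controller.
* **Benefit analysis** — psychometric functions (windowed detection; 50%
  point) and iso-autocorrelation matching of with-/without-noise AC-vs-
  threshold curves, both reporting a threshold benefit in dB.
* **Audiometric cohort** — synthetic tinnitus / non-tinnitus audiogram
  cohorts on the 5 dB clinical lattice and a tie-calibrated per-frequency
  two-sample Kolmogorov–Smirnov comparison.

## Worked example

A quiet environment (N(0, 5²) dB) against a 20 dB threshold — a genuinely
sub-threshold signal, the regime where SR operates:

```r
library(adaptsr)
env   <- env_config(mu_I = 0, sigma_I = 5, n_samples = 1e5, seed = 12)
par20 <- sensor_params(I_theta = 20, mu_I = 0, sigma_I = 5)

resonance_curve(env, par20, noise_grid = seq(0, 25, 0.5)^2,
                seed = 52, max_lag = 20)
#> Resonance curve: 51 noise levels, sigma_n in [0, 25.0] dB
#>   optimum: sigma_n^2 = 100.00 dB^2 (sigma_n = 10.00 dB), objective = 0.0194

run_feedback_loop(env, par20, feedback_controller(max_iter = 80),
                  seed = 2, max_lag = 20)
#> Feedback trajectory: 80 iterations, terminal sigma_n^2 = 102.18 dB^2, not converged
```

Without noise nothing crosses the threshold and the output autocorrelation
is zero; about 10 dB of noise sd transmits the most temporal structure
(mean AC ≈ 0.019), and the closed-loop controller finds the same level
(σ_n² ≈ 102 vs. 100 dB²) without ever seeing the grid search. Reading the
threshold benefit off the AC-vs-threshold curves:

```r
atc <- ac_threshold_curve(env, thresholds = seq(10, 34, 2),
                          base_params = sensor_params(mu_I = 0, sigma_I = 5),
                          noise_grid = seq(0, 25, 1)^2, seed = 7, max_lag = 20)
benefit_by_ac(30, atc)
#> [1] 6.32
```

At 30 dB of loss, optimally tuned noise transmits as much information as a
sensor with a ~24 dB threshold: a 6.3 dB benefit.

On the **adapted standard environment** (N(40, 25²)) the picture inverts:
a large share of the input is supra-threshold at any loss up to 60 dB, and
independent per-sample noise dilutes the output autocorrelation more than
it rescues the sub-threshold remainder:

```r
resonance_curve(env_config(n_samples = 1e5, seed = 1),
                sensor_params(I_theta = 20), seed = 2)
#> Resonance curve: 60 noise levels, sigma_n in [0, 75.0] dB
#>   optimum: sigma_n^2 = 0.00 dB^2 (sigma_n = 0.00 dB), objective = 0.1720
```

The located optimum is zero noise — so on this environment both benefit
estimators return 0 dB at every loss level. The vignette
(`vignettes/adaptive-stochastic-resonance.Rmd`) derives why, and documents
every tuning choice (time step, grids, lag counts, detection window,
controller, KS calibration).

## Command line

```sh
Rscript inst/cli/adaptsr.R simulate-env --mu 40 --sigma 25 --n 200000 --seed 1 --mode ou --out series.csv
Rscript inst/cli/adaptsr.R resonance --theta 20 --metric both --out curve.csv
Rscript inst/cli/adaptsr.R benefit --loss 20 --method both
Rscript inst/cli/adaptsr.R cohort --n 500 --seed 1 --out cohort.csv
Rscript inst/cli/adaptsr.R cohort-compare --in cohort.csv
```

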