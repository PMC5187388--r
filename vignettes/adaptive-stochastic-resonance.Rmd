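---
title: "An adaptive stochastic-resonance model of auditory detection thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive stochastic-resonance model of auditory detection thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptsr)
```

## The model in one paragraph

`adaptsr` simulates a single frequency channel of the auditory periphery as a
chain of four components: (1) an acoustic environment — a Gaussian
distribution of sound intensity levels, sampled as a temporally
autocorrelated trajectory; (2) a sensor, the inner-hair-cell/auditory-nerve
stage, which maps intensity to firing rate through a thresholded, infomax
(CDF-shaped) rate-intensity function; (3) an information detector that scores
the sensor output by its mean autocorrelation (a quantity a neural circuit
could plausibly compute with delay lines and coincidence detectors, unlike
mutual information); and (4) a noise generator that injects zero-mean white
Gaussian "internal noise" into the sensor input. Closing the loop —
adjusting the noise variance so the output autocorrelation is maximal — is
adaptive stochastic resonance (SR): for signals below the sensor threshold,
a non-zero noise level transmits the most information. Hearing loss is
modelled purely as an elevation of the sensor threshold `I_theta`; the
package quantifies how much of the lost detectability optimally tuned noise
can restore, in dB.

## The acoustic environment

Intensity levels `I(t)` (dB SPL) follow an Ornstein–Uhlenbeck process with
unit relaxation rate, stationary mean `mu_I = 40` dB and stationary standard
deviation `sigma_I = 25` dB, so the marginal distribution is N(40, 25²) and
the autocorrelation decays as `exp(-tau)` in model time units. A dB-Gaussian
corresponds to log-normally distributed linear amplitudes, a reasonable
description of everyday acoustic input. An i.i.d. series with the same
marginal serves as the uncorrelated control: identical density, completely
different autocorrelation.

Numerical choices (the SDE itself fixes neither):

* **Discretisation.** The exact transition
  `I(t+dt) = mu + (I(t)-mu)e^(-dt) + sigma*sqrt(1-e^(-2dt))*xi` is used, not
  Euler–Maruyama; it is stable and exact for any step.
* **Time step `dt = 0.1`** resolves the unit correlation time well;
  **`n_samples = 2e5`** gives sub-1% Monte-Carlo error on means and about
  0.002 standard error on a mean autocorrelation.
* The first sample is drawn from the stationary law, so there is no burn-in
  and every marginal is exactly N(mu, sigma²).
* All randomness flows through explicit `seed` arguments; functions restore
  the caller's RNG state.

## The sensor

Below threshold the fibre fires at the spontaneous rate `f_sp = 50` Hz;
above it, the rate follows the cumulative distribution of the adapted
intensity distribution, scaled to reach `f_max = 250` Hz:
equally probable intensities get equal shares of the rate range (infomax).
The CDF is evaluated analytically. Two modelling commitments:

* **No re-adaptation after damage.** Raising `I_theta` leaves `mu_I`,
  `sigma_I`, `f_sp`, `f_max` unchanged — hearing loss is threshold elevation
  and nothing else.
* **Rates are instantaneous analogue quantities**; there is no spike
  generation, refractoriness, or fibre heterogeneity.

With injected noise, each time sample receives an independent draw
`n ~ N(0, sigma_n²)` added to the intensity *before* thresholding (both the
threshold comparison and the CDF argument use `I + n`). Summed inputs are
not clamped below: the rate function already saturates at `f_sp`.

## Objectives: mean autocorrelation and mutual information

The information detector uses the lag-averaged normalised autocorrelation of
the output, `mean(AC(tau), tau = 1..N)`, with mean and variance taken over
the full series. A constant output (everything sub-threshold, no noise) has
an undefined quotient; the package defines its AC as zero — a constant
output transmits nothing. The lag count `N` defaults to 50 at native
sampling (five correlation times); the package's tests show the headline
benefit numbers move by less than 0.5 dB across `N` in {20, 50, 100}.
Mutual information between input and output is estimated from a 64×64
equal-width histogram (range clipped at mean ± 5 sd). The plug-in estimate
is positively biased at finite n, which is immaterial here: the resonance
analysis needs only the *location* of its maximum.

## Resonance curves and the noise optimum

`resonance_curve()` scans a grid of noise variances — 60 levels, equally
spaced in noise *sd* from 0 to three environment sd — and evaluates the
objective at each level. By default all levels share one environment
realisation and one standard-normal noise vector scaled per level (common
random numbers, CRN). This is a deliberate design choice: the argmax of a
nearly flat noisy curve estimated with independent realisations per level is
dominated by resampling jitter (spurious "optima" of a few dB that move with
the seed), whereas CRN cancels that jitter without biasing the curve — a
real peak is found more reliably, not hidden. `independent = TRUE` restores
per-level resampling. A 3-point moving average (switchable) guards the
argmax against residual roughness; exact ties break toward the smaller
noise level, and a curve that is zero everywhere returns the largest grid
level with a degeneracy flag.

`run_feedback_loop()` is the closed-loop counterpart: finite-difference hill
climbing on the noise sd with decaying steps, paired-CRN probes, projection
at zero, and one explicit rule — while the measured objective is below its
Monte-Carlo noise floor (output carrying no measurable signal), the
controller steps upward, because when nothing is transmitted more noise is
the only move that can help. The loop is a plausible realisation of the
feedback principle, not a prescribed algorithm, and is validated against the
grid search: in the package's tests its terminal noise level agrees with the
grid-search optimum to within 20%.

## Where stochastic resonance does — and does not — occur

Two regimes, both computed by the package's tests:

* **Fully sub-threshold signals** (e.g. a quiet N(0, 5²) environment against
  thresholds of 20–30 dB) show textbook SR: zero transmission without noise,
  an interior optimum (about 9 dB of noise sd for a 20 dB threshold), decline
  beyond it, onset and optimum shifting to larger noise and the attainable
  peak shrinking as the threshold rises. Iso-AC threshold benefits of
  several dB (about 2.4 dB at 26 dB loss, 6.3 dB at 30 dB loss in the
  bundled configuration) follow.
* **The adapted standard environment** behaves differently. With
  N(40, 25²) input, between 8% (at 0 dB) and 79% (at 60 dB) of intensities
  remain supra-threshold, and those samples already transmit strongly. An
  independent white-noise draw per sample adds variance that is uncorrelated
  across time: it dilutes the output autocorrelation at every lag while the
  sub-threshold samples it rescues transmit only weakly through a single
  noisy draw. The net effect is that the mean-AC and MI objectives are
  monotone non-increasing in the noise level at *every* threshold in
  0–60 dB, so the located optimum is zero noise and both benefit estimators
  return 0 dB. This is a property of the model as specified — white,
  per-sample noise and a full-series Pearson autocorrelation — not a
  simulation artefact; it persists at n = 2×10⁶ with CRN and across
  objective variants (autocovariance, binarised output, MI).

The practical reading: in this model, adaptively tuned internal noise
restores thresholds only for inputs that are (nearly) entirely
sub-threshold — profound loss relative to the signal, the classic SR
regime — and a mixed supra/sub-threshold environment is best served by no
added noise.

## Benefit estimators

* **Psychometric (detection) estimator.** A trial presents a constant probe
  for `window_m` noise samples and detects iff any summed sample crosses
  threshold; the 50% point of detection probability versus probe intensity
  is the behavioural threshold. A single symmetric draw cannot move the 50%
  point (p(I) = Phi((I−I_theta)/sigma_n) is centred on the threshold), so a
  multi-sample window is the minimal mechanism by which noise lowers the
  measured threshold: by `sigma_n * qnorm(0.5^(1/m))` dB. `window_m = 10` is
  the default; it is a reporting convention, not a fitted quantity. All
  probes share the simulated noise windows, so the curve is monotone by
  construction and the 50% point is an empirical median.
* **Iso-AC estimator.** From the with-/without-noise mean-AC-versus-threshold
  curves (0–60 dB in 2 dB steps, shared realisation), the benefit at loss L
  is the horizontal distance to the no-noise curve at equal AC, interpolated
  linearly on the strictly decreasing envelope of that curve (flat segments
  carry no iso-AC information and are excluded from the inversion).

## The synthetic audiometric cohort

`generate_cohort()` emulates the *structure* of a clinical pure-tone
audiometry dataset — 11 standard frequencies, 5 dB quantisation, a
[−10, 130] dB HL instrument range, tinnitus / non-tinnitus group labels —
with Gaussian per-frequency thresholds around a typical sloping
clinic-population baseline (spread 15 dB) and a per-frequency median offset
for the tinnitus group. It emulates no individual-level audiogram shapes,
no ear pairing (each record is treated independently), and no covariates
(age, sex), and nothing ties it quantitatively to the SR model: it exists so
the group-comparison machinery can be validated end-to-end.
`compare_groups()` reports per-frequency medians (midpoint convention) and
the two-sample Kolmogorov–Smirnov statistic. Because 5 dB quantisation
produces heavy ties, the asymptotic KS p-value is severely conservative
(measured null rejection ≈ 0.015 at alpha = 0.05); the default is therefore
a label-permutation p-value (199 permutations) for the same D statistic,
which restores nominal calibration, with the asymptotic value available as
an option.

## What the tests do and do not show

The suite verifies the generator against closed forms (OU moments,
exponential AC decay, KS agreement of marginals), the sensor against
independent Gaussian-CDF arithmetic, the estimators against analytic
oracles (Gaussian MI, windowed-detection psychometrics), the SR
phenomenology in the sub-threshold regime, the controller against the
grid-search oracle, and the cohort test's null calibration and power
ordering. All of this concerns synthetic signals with known structure; none
of it demonstrates anything about real cochlear signals, real audiograms, or
tinnitus patients.

## Known limitations

* Single frequency channel; no cross-frequency interactions.
* Analogue rate model: no spiking, adaptation dynamics, or fibre types.
* The feedback controller's timescale is arbitrary; only its fixed point is
  meaningful.
* The detection-window length `window_m` is a convention that scales the
  psychometric benefit linearly in `sigma_n`; it has no biophysical
  calibration.
* On the adapted standard environment the located noise optimum is zero
  (see above), so all benefit figures quoted for that environment are zero;
  non-trivial benefits arise only in sub-threshold configurations.
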