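---
title: "Models and methods behind stnsat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stnsat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`stnsat` studies a single scientific question end to end: how does the
subthalamic nucleus (STN) shape the speed–accuracy trade-off (SAT), and can
precisely timed bursts of deep-brain stimulation (DBS) dissociate the control
of *decision* speed from the control of *movement* speed? Because patient
recordings of this kind cannot be redistributed, the package ships a
synthetic experiment generator whose defaults mirror the study design, plus
the full analysis chain. This vignette documents the models, the assumptions
behind them, and the reasoning behind the main parameter choices.

## 1. The task and its synthetic counterpart

Each trial of the simulated task presents an instruction cue ("speed" or
"accuracy", balanced within session), followed after a 0.75–1.25 s jitter by
a moving-dots decision cue. The subject responds by squeezing a left or right
force grip; the response is registered when force crosses 20 N. Behavioral
outcome measures are the reaction time (RT, cue to movement onset), movement
time (MT, movement onset to the force trigger), response accuracy, and peak
force.

`simulate_experiment()` composes:

* **Decision behavior** from a drift-diffusion process (Euler–Maruyama at
  1 ms steps with a Brownian-bridge within-step absorption correction so that
  simulated first-passage times agree with the analytic density; without the
  correction, discrete stepping systematically misses within-step boundary
  crossings and inflates RTs by O(√dt)).
* **Movement behavior** as instruction-dependent movement times with a
  negative dependence on the trial's decision threshold (faster movements
  after more accumulated evidence).
* **Grip-force traces** as sigmoidal rise to a peak with sensor noise, from
  which onset detection and trial measures can be re-derived.
* **STN LFPs** per hemisphere and contact: 1/f background, beta (13–30 Hz)
  rhythm with cue-locked and movement-locked suppression, movement-locked
  gamma (55–80 Hz) bursts concentrated on one "best" contact, theta
  activity, 50 Hz line noise, and — during stimulation sessions — a biphasic
  130 Hz pulse-train artifact with ramped amplitude.
* **Burst stimulation schedules**: plateaus drawn from U(150, 350) ms flanked
  by 150 ms linear ramps, separated by U(75, 225) ms intervals, bilateral or
  unilateral. The ramps are treated as "no stimulation" throughout the
  analysis; only the plateau counts as clinically effective.

The generator draws every component from an independent, seed-derived
sub-stream, so adding the LFP component never changes the behavioral
realization — a property the test suite checks.

Key calibration choices (all made against the published behavioral and
electrophysiological observables *before* any acceptance run):

* threshold ≈ 2 (accuracy) with a multiplicative −0.26 log-shift under speed
  emphasis, drift ≈ 0.6, non-decision time ≈ 0.3 s — producing accuracy
  around 65% and right-skewed RT distributions typical of the patient group;
* stimulation effects on the threshold of −0.20 (accuracy trials) / +0.10
  (speed trials) when a plateau falls 180–10 ms before the cue, and −30 ms of
  movement time when it falls 330–460 ms after the cue. These are the
  *latent* shifts needed so that the *measured*, window-conditioned
  behavioral differences match the published post-hoc effect sizes; the
  measured effect is diluted because any 100 ms analysis window also counts
  trials whose plateau only grazes it;
* an LFP beta–threshold coupling strong enough that the single-trial
  regression of threshold on cue-related beta suppression recovers a
  coefficient inside the published credible interval at 13 subjects.

## 2. Behavioral exclusions and hierarchical regressions

`filter_trials()` flags omissions (no response before the deadline), double
responses, and implausibly fast responses (RT < 250 ms), and keeps everything
else. `prepare_behavior()` sum-codes instruction (−0.5 = accuracy, +0.5 =
speed) and takes logs of RT and MT, whose residuals are closer to normal.

`fit_hlm()` and `fit_hlogit()` fit Bayesian hierarchical regressions through
JAGS: population-level fixed effects, by-subject random intercepts with a
half-normal standard-deviation prior, and a Gaussian (log-outcome) or
Bernoulli-logit likelihood. Convergence is monitored with split-R-hat over
multiple dispersed chains; `decide_significance()` implements the decision
rule used throughout: a two-tailed 95% highest-density interval excluding
zero, or a one-tailed 90% interval when a direction is pre-specified.

## 3. The hierarchical drift-diffusion model

The DDM is authored from scratch (`R/ddm.R`, `src/wfpt.cpp`):

* **Likelihood**: the Wiener first-passage-time density, evaluated with the
  standard small-time/large-time series decomposition, selecting whichever
  representation needs fewer terms for a truncation error below 10⁻⁷. The
  lower-boundary density is the upper-boundary density with drift and start
  point reflected. Hitting probabilities use an `expm1`-based closed form
  stable at small drifts.
* **Trial-level structure**: threshold, drift and non-decision time each get
  a linear model `subject intercept + X β` built from an R formula, so
  instruction effects and covariates (e.g. single-trial beta power, z-scored
  within subject) enter exactly where the scientific question demands.
* **Sampling**: blocked adaptive Metropolis-within-Gibbs in C++ — subject
  parameters, fixed-effect coefficients, and group-level means/SDs updated in
  turn, with proposal scales adapted during burn-in. Chains start from
  dispersed EZ-diffusion method-of-moments estimates. Split-R-hat ≤ 1.1
  across chains on all reported terms is required before a fit is flagged
  `converged`.
* **Checks**: `quantile_probability_check()` compares observed RT percentiles
  and response probabilities per condition against posterior-predictive
  simulations.

The package's parameter-recovery study (acceptance criterion 3) uses 13
subjects × 180 trials and verifies ≥90% credible-interval coverage for both
an injected instruction effect and a trial-level covariate effect on the
threshold. The recovery data are simulated *from the fitted model class*:
trial-level threshold jitter is disabled, deadlines are relaxed, and the
between-subject threshold SD is kept small, because a recovery study is only
interpretable when the estimand is well-defined under the fitted model —
with the generator's full realism switched on, deadline censoring and
unmodeled trial noise attenuate the covariate slope, which is a robustness
observation rather than a correctness criterion.

## 4. Spectral analysis

`preprocess_lfp()` high-passes at 1 Hz, removes 49–51 Hz line noise,
low-passes at 100 Hz, and resamples to 200 Hz. `bipolar_montage()` derives
bipolar channels from the contact labels: adjacent-level pairs (3 channels on
a quadripolar lead, 9 on a 1-3-3-1 directional lead counting within-level
segments), or a wide first-to-last-level scheme.

`morlet_tfr()` convolves with unit-energy 7-cycle complex Morlet wavelets via
FFT, evaluates power on a 20 ms grid, and masks the first and last 3
temporal-SDs per frequency as edge-invalid rather than returning contaminated
values. `normalize_power()` expresses power as percent change from the
whole-recording time-mean per frequency — exactly zero-mean by construction,
which the tests assert to 10⁻¹⁰.

Single-trial features (`extract_features()`): `beta_cue` (pre-cue 300–100 ms
minus post-cue 320–400 ms beta, positive = stronger suppression),
`beta_move` and `gamma_move` (0–300 ms after movement onset), `theta_cue`
(0–750 ms post-cue). Contact selection uses movement gamma as a functional
localizer with a beta-suppression fallback. Outlier flags (|z| > 3) and
RT-conditional exclusions (RT ≥ 400 ms for `beta_cue`, ≥ 750 ms for
`theta_cue` when predicting RT) mirror the study's control analyses.

## 5. Timing-resolved stimulation analysis

`assign_windows()` slides a 100 ms window in 10 ms steps across −500…+1000 ms
around the cue (or −1000…+500 ms around movement onset) — 141 windows — and
flags each trial per window if any plateau sample falls inside the half-open
window interval. Per-window effects across subjects (stimulated minus
unstimulated outcome, or the SAT-difference interaction) feed
`cluster_permutation()`: adjacent same-sign supra-threshold windows form
clusters whose summed t-mass is compared to a max-statistic null obtained by
flipping the sign of whole subject time-courses, preserving temporal
autocorrelation. With J ≤ log₂(n_perm) subjects all 2^J sign assignments are
enumerated exactly. Post-hoc condition-wise tests, a DBS-as-threshold-
predictor DDM refit, and unilateral contralateral/ipsilateral contrasts
follow the significant spans.

`remove_stim_artifact()` removes the pulse-train artifact by filtering to the
analysis band and interpolating samples exceeding an amplitude threshold
(with padding), aborting if more than half the recording would be
fabricated. The generator's artifact amplitude default is set so that
removal is exercised (≈2% of samples interpolated) while inter-burst beta
power stays within a few per mil of the artifact-free ground truth.

## 6. Pipeline, IO and problem sizes

`run_pipeline()` wires the stages together behind a validated YAML-round-trip
configuration and produces a deterministic report (identical config + seed ⇒
bit-identical report). `write_dataset()`/`read_dataset()` serialize a
dataset losslessly (Feather for signals and tables, CSV events for
interoperability, maximum-precision JSON metadata).

Default problem sizes are the package's own choice, set to keep the full
test suite within a desktop-CI budget while remaining statistically
meaningful: pipeline defaults of 8 subjects × 120 trials with 500
permutations and 2 × 2500 MCMC draws; `paper_scale = TRUE` switches to the
study dimensions (13 subjects, 200 trials, 1000 permutations, 3 × 10000
draws). Acceptance runs use 13-subject, 120–200-trial simulations with
reduced LFP sampling rates (512 Hz) and band-restricted frequency grids,
which change runtime but not the analysis logic.

## 7. What the generator does and does not claim

The generator reproduces the *structure* of the study — timing, schedule
statistics, coupling directions, realistic effect and noise magnitudes — and
is calibrated so that headline analyses recover published effect directions
and orders of magnitude at matched sample sizes. It does not model
between-session nonstationarity, electrode impedance drift, or
instruction-level differences in cue-related beta beyond those induced by
the threshold coupling; published group-level numbers derived from patient
data are targets for sign and rough magnitude, not for exact reproduction.
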