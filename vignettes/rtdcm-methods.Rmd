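---
title: "Near real-time DCM for connectivity neurofeedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Near real-time DCM for connectivity neurofeedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtdcm)
```

## The problem

Classical fMRI neurofeedback trains self-regulation of *activity* in one
region of interest. `rtdcm` implements the machinery for feedback on
*effective connectivity*: the participant's task is to make one predefined
network model dominate over another, and the feedback signal is the log
Bayes factor between the two models, recomputed after every trial from a
sliding window of ROI time courses. The reference paradigm is covert
visual-spatial attention over a four-region network — left and right early
visual cortex (VC) and superior parietal lobule (SPL) — where attention to
the left engages the right hemisphere's VC↔SPL coupling and vice versa.

## Generative model

### Neuronal level

Regional activity follows the bilinear state equation

$$\dot z = \Big(A + \sum_j u_j B^{(j)}\Big) z + C u,$$

with intrinsic couplings $A$ (Hz), input-dependent modulations $B^{(j)}$ and
direct input weights $C$. The network structure is fixed across all
candidate models: reciprocal VC↔SPL coupling within each hemisphere and no
interhemispheric connections. Self-connections are parameterized as
$-0.5\,e^{a_{ii}}$ Hz, so every estimated model has strictly decaying
intrinsic dynamics; `max_eigen_real()` can certify stability before a
simulation.

### Hemodynamics and observation

Each region's neuronal activity drives a balloon–Windkessel cascade
(vasodilatory signal $s$, inflow $f$, venous volume $v$,
deoxyhemoglobin $q$):

$$\dot s = z - \kappa s - \gamma(f - 1), \quad \dot f = s, \quad
\tau \dot v = f - v^{1/\alpha}, \quad
\tau \dot q = f\,\frac{E(f,\rho)}{\rho} - v^{1/\alpha}\frac{q}{v},$$

with $E(f,\rho) = 1 - (1-\rho)^{1/f}$, and the BOLD observation

$$y = V_0\left[k_1(1 - q) + k_2\left(1 - \tfrac{q}{v}\right) +
k_3(1 - v)\right].$$

Defaults are the classical constants $\kappa = 0.64$, $\gamma = 0.32$,
$\tau = 2$ s, $\alpha = 0.32$, $\rho = 0.32$, $V_0 = 0.04$, $k_1 = 7\rho$,
$k_2 = 2$, $k_3 = 2\rho - 0.2$. The interface reports percent signal change
($100\,y$).

### Integration

The coupled system is integrated from rest by fixed-step RK4 with
`dt = TR/8` by default and zero-order-hold inputs; BOLD is sampled at each
volume onset (no slice-timing offset — a declared convention, since either
choice only shifts the sampling grid). RK4 makes the step-halving error
ratio testable (about $2^4$), and halving the default step changes the
default trial simulation by less than $10^{-4}$ percent signal. Any
neuronal state exceeding a bound (default 10) aborts with a divergence
error; during inversion such parameter proposals are treated as rejected
steps.

## Model space

`attention_pair()` builds the two feedback models: `M_aL` places the
attention input on the right SPL and lets attention modulate the reciprocal
right VC↔SPL coupling; `M_aR` is the left-hemisphere mirror image.
`model_family()` spans the 3 × 4 comparison family — input into SPL, VC or
both, crossed with modulation of both directions, top-down only, bottom-up
only, or none; family member 1 is the neurofeedback architecture.
Whether the experimental modulation acts on one or both directions of the
VC↔SPL pair is ambiguous at the network level, so "both" is the default
pattern and the single-direction variants are explicit family members.
There is a single external input channel (attention): the paradigm presents
no other visual stimulation, so no sensory channel is modeled.

## Variational Laplace inversion

`invert()` fits the free couplings (self-decay log-scales, off-diagonal A,
B, C) by Gauss–Newton ascent on the free-energy bound

$$F = \underbrace{E_q[\log p(y \mid \theta, \lambda)]}_{\text{accuracy}}
  - \underbrace{KL[q(\theta)\,\|\,p(\theta)]
  + KL[q(\lambda)\,\|\,p(\lambda)]}_{\text{complexity}},$$

with per-region iid Gaussian noise of log precision $\lambda$ updated by an
EM (Newton) step each iteration. Hemodynamic constants are fixed at their
nominal values: in a 90-scan window the coupling parameters are the
identifiable quantities of interest, and freeing regional transit times
adds little beyond variance. Design choices that matter:

* **Priors.** Zero-mean shrinkage priors, variance 1/4 on free A/B/C
  entries (couplings of a few tenths of a Hz are plausible), 1/64 on the
  self log-scales, and a weak `N(0, 16)` prior on each $\lambda$.
  Structurally absent connections are not parameters at all — exactly zero
  with zero prior variance.
* **Confounds.** A per-window constant plus linear drift basis is projected
  out of data and prediction alike; the effective degrees of freedom are
  reduced accordingly.
* **Jacobians** by central finite differences (relative step $10^{-4}$);
  **damping** is Levenberg-style (×2 on a rejected step, ÷2 on acceptance),
  so the recorded free-energy trajectory is non-decreasing. The whole
  scheme is deterministic — identical inputs give bit-identical results.
* **Budget.** The iteration cap defaults to 44, the real-time budget that
  fits a model comparison into a 60 s inter-trial rest block; convergence
  is declared when $|\Delta F| < 0.05$ nats on two consecutive iterations
  (the cap is the operating constraint of the original system; the
  tolerance is this package's choice and is configurable). With
  `max_iter = 0` the posterior is the prior, flagged unconverged. Because
  budgets only truncate a deterministic iteration sequence, the fit at the
  cap is an exact prefix of the converged fit — the package exploits this
  to compare capped and converged log Bayes factors from one run.

On a linear-Gaussian surrogate the implementation attains the analytic log
evidence to better than $10^{-6}$ nats (the test suite checks $10^{-13}$),
which pins down the accuracy/complexity bookkeeping exactly.

### What the noise model assumes

The iid Gaussian noise assumption is deliberate: temporal autocorrelation
is *not* modeled, matching a real-time setting where a causal cleaner, not
a GLS whitener, conditions the signal. Consequence: on data whose noise is
AR(1)-correlated the posterior is mildly overconfident (roughly the
low-frequency variance inflation $(1+\phi)/(1-\phi)$), and 90% credible
intervals cover at about 77% rather than 90% at $\phi = 0.3$. Calibration
statements about credible intervals therefore use the model's own noise
assumption (white noise at the default level); model *selection* between
the mirrored pair is insensitive to this, because the miscalibration is
symmetric.

## Bayesian model comparison and group inference

The feedback statistic is $\log BF = F_{M_{aL}} - F_{M_{aR}}$; positive
values mean the attention-left model dominates. Bayes factors are binned
into the standard evidence categories (weak ≤ 3 < positive ≤ 20 < strong).
`rfx_bms()` implements random-effects Bayesian model selection: a
variational Dirichlet model over per-subject model frequencies (uniform
prior $\alpha_0 = 1$) fitted from log evidences, with exceedance
probabilities computed exactly through the Beta distribution for two models
and by seeded Dirichlet sampling ($10^5$ draws by default) otherwise.
Per-subject evidences for a condition are obtained by summing log Bayes
factors over that subject's trials; treating each trial as a subject is
available as the caller's choice of input matrix.

## The streaming pipeline

`clean_sample()` is strictly causal and processes one scan at a time (the
offline `clean_series()` is literally the same code path, so streaming and
offline outputs are bit-identical):

1. **Drift removal** subtracts an exponentially-weighted running *linear*
   fit (recursive least squares with forgetting factor $2^{-1/50}$ per
   scan). A running linear fit, unlike a running mean, tracks ramps with
   zero steady-state lag, so constants and scanner drifts are removed
   without leaving a warm-up slope in the output.
2. **Despiking** replaces samples more than 3 robust SD
   ($1.4826 \times$ MAD over the trailing 50 scans) from the running median
   by that median. The median/MAD buffer keeps the *raw* residuals so the
   scale estimate can adapt to genuine signal swings — otherwise clipping
   becomes self-perpetuating after each quiet rest block and removes the
   response onsets it is meant to protect. The drift tracker is updated
   with the clipped value, so spikes do not corrupt the running fit.
3. **Smoothing** by a two-tap exponential moving average (weight 0.6 on the
   current sample) attenuates high-frequency noise.

`run_session()` threads the stream through the cleaner, extracts each
trial's 90-scan window (5 baseline + 4 regulation blocks; rest and display
scans never enter the inversion), inverts the pair under the 44-iteration
budget, and emits one feedback event per trial: UP/DOWN word, the log Bayes
factor rounded half away from zero, success flag (ties are failures), and
the cumulative 1-CHF-per-success reward. `window_sweep()` reproduces the
operating-point analysis: window lengths 30–210 in steps of 20 slid across
a run in 20-scan steps, scoring per window whether the dominant model
matches the condition and summarizing the aligned log Bayes factors with
the one-tailed sign test.

`glm_localizer()` stands in for the ROI-defining localizer analysis: a
per-voxel GLM with a canonical double-gamma HRF regressor, constant and
drift, one-sided t statistics and Bonferroni correction across voxels.

## Synthetic data: what it emulates, and what it does not

`simulate_session()` generates ground-truth sessions: block designs at
TR = 1 s (neurofeedback trials of 90 scans plus 60 s rest and 5 s display;
210-scan localizer runs), BOLD from a two-channel truth model (attention
left/right acting on the contralateral hemisphere), and noise with the
structure the cleaner must face — AR(1)-filtered white noise (innovation sd
0.5% of baseline, coefficient 0.3), linear drift (0.01%/scan) and sparse
8-SD spikes (probability 0.005/scan). The raw scale is percent of a
baseline level of 100, so percent-signal-change baselines are meaningful.

Two generator conventions deserve emphasis:

* **Truth modulates the top-down connection only.** At the default
  magnitudes (intrinsic 0.3 Hz, modulation 0.4 Hz, self-decay 0.5 Hz),
  modulating *both* directions of a reciprocal pair gives the regulated
  subsystem a positive eigenvalue (+0.2) — the simulated network would
  diverge during regulation blocks. Placing the generative modulation
  top-down keeps the slowest regulated mode stable while the candidate
  models still estimate both directions (and recover a bottom-up effect
  near zero). Attention effects on visual cortex are standardly described
  as top-down, so this is also the physiologically natural choice.
* **Baseline counting is zero input.** Whether counting backwards engages
  the attention network is unknowable from behavioral descriptions alone;
  baseline blocks carry no input.

What passing tests on these data do **not** show about real data: the
generator has no head motion, no cardiac/respiratory waveforms, no regional
differences in hemodynamics, and its effect sizes produce much larger
trial-wise log Bayes factors (hundreds of nats) than human participants do
(single-digit medians). Recovery and calibration results are statements
about the implementation, not about expected human performance.

## Numerical choices and degenerate inputs

* Quartiles by linear interpolation (type 7); the original box-plot
  convention is not stated anywhere, so the R default is used.
* The sign test excludes exact zeros and uses the continuity-corrected
  normal approximation $z = (k - 0.5 - n/2)/\sqrt{n/4}$, with p-values from
  the *unrounded* z — both are required to reproduce every printed
  statistic of the reference results.
* Permutation p-values use the add-one rule $(1 + \#\{\ge\})/(N+1)$, so
  they are never below $1/(N+1)$.
* Display rounding is half-away-from-zero (so $-4.2$ displays as $-4$ and
  $+0.5$ as $+1$).
* Ties ($\log BF = 0$) are failures — the conservative reading of the
  reward rule.
* Degenerate inputs error loudly: non-finite samples in the stream (with
  scan and region), baseline means of zero in percent signal change, zero
  baseline variance in CNR, divergent simulations (with the divergence
  time), fewer than two models in RFX-BMS, unknown configuration keys.

## Problem sizes used in the shipped checks

The package's own acceptance checks run at desk scale, chosen to keep the
whole suite in minutes while leaving the binomial bands meaningful: 50
seeded single-trial recoveries for coverage/model-selection rates (each
trial 90 scans, both models fit to convergence), 200 pure-noise trials for
null calibration, $10^5$-draw exceedance sampling against a $10^6$-draw
Monte-Carlo oracle, and 200-scan streams for the cleaner oracles. The
measured outcomes on these conditions: coverage of 90% credible intervals
0.90–0.91, correct-model rate 1.0, capped-vs-converged sign agreement 1.0,
null dominance rate 0.50 ± binomial error.

## Known limitations

* No temporal autocorrelation in the observation model (see above); no
  AR-aware free-energy correction.
* Hemodynamic parameters are fixed rather than estimated; regionally
  heterogeneous hemodynamics would be partially absorbed by couplings.
* The variational posterior is a single Gaussian mode; multimodality in
  coupling space (e.g. sign flips between excitatory/inhibitory readings)
  is not represented.
* The sweep labels mixed-condition windows by majority condition and skips
  ties; the original localizer analysis's exact handling of windows
  straddling conditions is not stated anywhere.
* Two-state neuronal models, stochastic DCM and EEG variants are out of
  scope.
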