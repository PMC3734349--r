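# rtdcm

Near real-time dynamic causal modeling (DCM) for connectivity-based fMRI
neurofeedback.

Most fMRI neurofeedback targets *activity* in a single region. This package
implements the alternative of feeding back *effective connectivity*: two
candidate network models are inverted against a sliding window of ROI time
courses after every trial, and the feedback signal is the log Bayes factor
between them. The reference paradigm is covert visual-spatial attention
over a four-region network — left/right early visual cortex (VC) and
left/right superior parietal lobule (SPL) — where attention to the left
should strengthen the right hemisphere's VC↔SPL coupling (model `M_aL`)
and attention to the right the left hemisphere's (`M_aR`).

## What is inside

* **Forward model** — bilinear neuronal dynamics
  `ż = (A + Σⱼ uⱼ B⁽ʲ⁾) z + C u` coupled to a balloon–Windkessel
  hemodynamic cascade with the standard BOLD observation
  `y = V₀[k₁(1−q) + k₂(1−q/v) + k₃(1−v)]`, integrated by fixed-step RK4
  (compiled, Rcpp).
* **Inversion** — variational Laplace (Gauss–Newton ascent on the free
  energy `F = accuracy − complexity`) with Levenberg-style damping, EM
  noise updates, per-window confound projection, and a real-time iteration
  budget (default cap: 44 iterations per model).
* **Model space** — the `M_aL`/`M_aR` neurofeedback pair and the 12-model
  comparison family (input into SPL/VC/both × modulation both/top-down/
  bottom-up/none).
* **Model comparison** — log Bayes factors, evidence categories
  (weak ≤ 3 < positive ≤ 20 < strong), and random-effects Bayesian model
  selection with exceedance probabilities (exact Beta closed form for two
  models, seeded Dirichlet sampling otherwise).
* **Streaming pipeline** — a strictly causal cleaner (running-linear drift
  removal, robust despiking, EMA smoothing), trial windowing, per-trial
  feedback events with display/reward semantics, the sliding-window
  optimization sweep, and a simple GLM localizer for ROI masks.
* **Offline statistics** — continuity-corrected sign test, descriptive
  summaries, permutation slope tests across runs, Jarque–Bera normality
  check, percent signal change, contrast-to-noise ratio, and differential
  (left-minus-right) activity feedback.
* **Synthetic data** — seeded generators for designs, ground-truth
  sessions (AR(1) noise, drift, spikes) and small 4D volumes with region
  masks, so every stage is testable without scanner data.

See `vignettes/rtdcm-methods.Rmd` for the models, assumptions and design
choices.

## Worked example

Simulate a four-trial neurofeedback session with ground-truth connectivity
and run it through the full streaming pipeline:

```r
library(rtdcm)

design <- make_design("neurofeedback", n_trials = 4)   # aL/aR alternating
sim    <- simulate_session(design, seed = 42)          # raw ROI stream
log    <- run_session(sim$series, design)              # clean + invert + feedback
print(log)
#> Session log: 4 trials, total reward 4 CHF
#> trial 1 [aL]: UP (+60)  logBF = 59.80  success  reward = 1 CHF
#> trial 2 [aR]: DOWN (-46)  logBF = -46.22  success  reward = 2 CHF
#> trial 3 [aL]: UP (+16)  logBF = 15.67  success  reward = 3 CHF
#> trial 4 [aR]: DOWN (-25)  logBF = -24.76  success  reward = 4 CHF
```

Each event shows the displayed word (UP for attention-left trials, DOWN
for attention-right), the rounded log Bayes factor, and the cumulative
1-CHF-per-success reward. Positive log Bayes factors mean the
attention-left model dominates; for pooled analysis the attention-right
values are sign-inverted, so positive always means "correct model won":

```r
pooled <- vapply(log, function(e) e$pooled_logBF, numeric(1))
print(sign_test(pooled))
#> sign test: sign = 4 of n = 4, z = 1.50, p = 0.067
```

The same statistic applied to a published success count — 97 positive
pooled log Bayes factors out of 168 trials — reproduces the familiar
z ≈ 1.93:

```r
print(sign_test(k = 97, n = 168))
#> sign test: sign = 97 of n = 168, z = 1.93, p = 0.027
```

A command-line wrapper over the same functions ships in
`inst/cli/rtdcm.R` with `simulate`, `clean`, `feedback`, `run-session`,
`sweep`, `localize`, `bms` and `stats` subcommands.

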