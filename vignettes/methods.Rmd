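---
title: "Decay-based recurrent risk prediction for irregular ICU time series: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decay-based recurrent risk prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(icugrud)
```

This vignette is the package's account of its science: the model and its
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic cohort generator does and does not emulate, the
numerical choices, and the places where the design was genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The prediction problem

A patient in intensive care produces an irregular multivariate time
series: heart rate and blood pressures nearly every hour, laboratory
values such as lactate or pH only when a clinician orders them (70–80%
of hours have no value), ordinal sedation/consciousness scores every few
hours, and medication administrations as point events. The task is a
*per-hour* risk: at every hour of the stay the model emits the
probability that the adverse event — for the motivating application, a
pressure ulcer — occurs now (on-time) or within a lead time of 12, 24 or
48 hours (in-advance). In-advance labels are constructed by shifting:
for horizon $h$, hours $\max(1, t_e - h)$ through the event hour $t_e$
are positive, and event stays are truncated at $t_e$ (post-event hours
carry no prediction task). An event at hour 60 with $h = 24$ therefore
has its first positive label at hour 36. Control stays are entirely
negative over their full length.

## 2. Grids, masks and staleness

`resample_hourly()` turns the long event table into per-patient
`T × D` matrices covering each whole hour of the stay (hour $t$ spans
$[t-1, t)$ hours since admission). Within-hour aggregation is
type-specific: mean for continuous variables, the *worst* category for
ordinal scales (severity order declared in the schema, worst first and
coded 1), and presence/absence for medications. Alongside the values
the pipeline maintains the observation mask $m_{t,d}$ and the staleness
matrix $\delta_{t,d}$ — hours since variable $d$ was last observed, with
$\delta_{1,d} = 0$ and $\delta_{t,d} = 1 + \delta_{t-1,d}$ when the
previous hour was unobserved. A never-observed variable keeps
accumulating staleness from admission; nothing downstream assumes any
variable is ever observed.

Preprocessing statistics are fitted **only** on training patients and
applied unchanged everywhere (this separation is enforced by the
fit/apply API and tested by perturbing validation data):

* **Tukey IQR fences** (`Q1 − 1.5·IQR`, `Q3 + 1.5·IQR`; quartiles by
  linear interpolation between order statistics) discard recording
  errors on continuous variables. "Discard" converts the cell to
  missing rather than dropping the hour, preserving grid alignment.
  Ordinal codes and binary medications have no meaningful fences. On an
  already-scaled grid the fences are applied in scaled space so the
  filter commutes with scaling and the pipeline is idempotent.
* **Min–max scaling** to $[-1, 1]$: training minimum $\mapsto -1$,
  maximum $\mapsto +1$. Non-training values may fall outside and are
  deliberately *not* clipped — an out-of-range reading is signal, not
  noise. A zero-range variable maps to constant 0 with a warning.
  Medication channels are scaled on the fixed range $[0, 1]$: a
  "no record" hour is a genuine 0, and fitting the range on observed
  records alone (all of which are 1) would be degenerate.
* **Forward-then-mean filling** supplies the complete inputs required
  by models without internal imputation: each missing cell takes the
  most recent earlier observation; cells before the first observation
  take the training mean of scaled values. The mask is untouched, so
  decay models can still distinguish imputed from observed cells.

## 3. The recurrent cells

All variants share one compiled engine (forward pass plus analytic
backpropagation through time, verified against central finite
differences to ~1e-10 in the test suite), differentiated by flags.

**Decay.** $\gamma = \exp\{-\max(0, w\delta + b)\}$, applied per
variable to the stale last observation ($\gamma^x$, one rate per
variable) and per hidden unit to the hidden state
($\gamma^h = \exp\{-\max(0, W_\gamma \delta + b_\gamma)\}$). The ReLU
keeps $\gamma \in (0, 1]$: information can only fade, never amplify.

**GRU-D.** A missing input is imputed as
$\hat{x} = \gamma^x \tilde{x}_{t'} + (1-\gamma^x)\bar{x}$ where
$\tilde{x}_{t'}$ is the last observation and $\bar{x}$ the frozen
training mean: recent observations dominate while fresh, the
population mean takes over as staleness grows. Because the textbook
formulation has no last observation before the first record, the last
observation is seeded with $\bar{x}$ so every output is finite even for
a variable missing an entire stay.

**GRU-D++.** Two changes make imputation fully trainable and
well-defined under missing *first* observations, the regime that
dominates when a lab is 80% missing:

1. the pre-observation seed is a trainable per-variable parameter
   $x_{\mathrm{init}}$, and
2. the static fallback is replaced by a hidden-state imputation head
   $r_t = W_{\mathrm{imp}} h_{t-1} + b_{\mathrm{imp}}$, trained jointly
   with the classifier through a masked reconstruction term
   $\sum m \odot (x - r)^2 / \sum m$ added to the loss with weight
   $\lambda$ — a single-phase, end-to-end alternative to two-stage
   impute-then-classify pipelines. The head performs cross-channel,
   cross-time inference: a missing lactate is estimated from everything
   the hidden state has absorbed.

Both components are independently switchable (`variant_flags()`):
`"grud_trainable"` keeps the static fallback but makes it a trainable
vector $\tilde{x}$, which also lets alternative published
parameterisations be matched later. As $\delta \to 0$ the imputed value
approaches the last observation; as $\delta \to \infty$ it approaches
the fallback ($\bar{x}$, $\tilde{x}$ or $r_t$ by variant) — both limits
are asserted in the tests, the latter at $\delta = 10^6$.

**Gates.** With $\hat{h}_{t-1} = \gamma^h \odot h_{t-1}$:
$z = \sigma(W_z\hat{x} + U_z\hat{h} + V_z m + b_z)$ (update),
$r = \sigma(\cdot)$ (reset),
$c = \tanh(W_c\hat{x} + U_c(r \odot \hat{h}) + V_c m + b_c)$, and
$h_t = (1-z)\odot\hat{h} + z\odot c$. The mask enters the gates through
the $V$ projections, so *that* something was unmeasured is itself
input. With decay disabled, full masks, and zero mask projections the
cell reduces exactly (max abs difference < 1e-6, tested over random
weight draws) to a plain GRU in the same convention — which is also the
mean-fill GRU baseline. A simple tanh RNN shares the engine; a one-hour
logistic regression over filled rows is the non-temporal baseline.

**Loss and training.** Per patient the loss is
$\frac{1}{T}\sum_t w_t\,\mathrm{BCE}(p_t, y_t) + \lambda\,
\sum_t m\odot(x-r)^2 / \sum_t m$, averaged over patients, with
$w_t = w_{\mathrm{pos}}$ on positive hours. Defaults: $\lambda = 0.1$
(reconstruction as a regularising auxiliary, not the main objective);
$w_{\mathrm{pos}} = $ inverse prevalence of positive training hours
(floored at 1), the standard imbalance correction; Adam at learning
rate 1e-3, batch 32, at most 50 epochs with early stopping (patience 5)
on model-selection AUROC — risk vs label pooled over every hour of the
model-selection split, a better-powered selection signal than the
handful of event hours alone. Gate weights initialise uniformly in
$\pm 1/\sqrt{H}$; $x_{\mathrm{init}}$, $\tilde{x}$, biases and $h_0$ at
0 (the centre of the scaled space); input-decay rates at 0.05/hour
(observation half-life ≈ 14 h, a gentle prior that staleness matters);
hidden-decay weights near 0. Hidden size defaults to $H = 64$;
the bundled benchmarks use $H = 32$ and capped epochs purely to fit a
single-CPU time budget.

## 4. Evaluation

`evaluate_horizons()` scores, for each horizon $h$, every event
patient's risk at $t_e - h$ (events inside the first $h$ hours are
skipped and counted) against **one** risk per control patient, drawn at
an hour sampled from the empirical distribution of the positive
evaluation hours restricted to hours that control actually has. The
time-matching is deliberate: per-hour risk tends to drift over a stay,
so pooling arbitrary control hours would let stay length masquerade as
discrimination. The draw is seeded and the scheme recorded in the
report. AUROC is the exact rank statistic (ties one half) — invariant
to monotone transforms of the scores; AUPRC is step-interpolated
average precision with tied scores grouped. Both match brute-force
oracles in the test suite.

`rank_variables()` estimates sampling-based Shapley importances: over
seeded random permutations, the marginal change in pooled AUROC when a
variable's observations join the coalition, with out-of-coalition
variables fully masked (mask 0, staleness recomputed). Masked cells
thus flow through the imputation path, so importance credits the
*observations*, not the imputer. Sampling Shapley was chosen over
gradient approximations to stay meaningful for every baseline,
including non-differentiable ones.

## 5. The synthetic cohort generator

`simulate_cohort()` produces the statistical regime the method assumes,
with ground truth retained for imputation scoring:

* a latent illness state $z_t$ per patient, stationary AR(1) with
  $\rho = 0.85$ and unit variance — an hourly autocorrelation half-life
  of roughly four hours, fast enough that stale observations genuinely
  mislead;
* a per-hour event hazard, logistic in $z_t$ (slope 1.5) plus 0.3 per
  day of stay (pressure-injury risk accumulates with time in bed); the
  intercept is calibrated by root finding against the realised latent
  paths so the expected fraction of event patients hits the target
  (default 4%, the order of magnitude of real ICU pressure-ulcer
  cohorts); an unreachable target raises an error reporting the
  attainable prevalence;
* a deterministic deterioration drift of 1.5 latent SD ramping linearly
  over the 72 hours before the event. The onset lead deliberately
  exceeds the longest (48 h) evaluation horizon: with a shorter ramp
  there would be nothing to learn at the longest horizon, defeating the
  generator's purpose;
* twelve observables mapped to clinical units: three nearly-complete
  vital-like channels that are weak, noisy correlates of $z$
  (loading ~0.25–0.35 against unit noise), six lab-like channels that
  are the strongest markers (lactate-like loading 1.2 at 80% missing,
  pH-like −1.0 at 72%, four more at 30–50%), one ordinal consciousness
  scale, and two state-dependent medication channels. Putting the
  signal in the sparse labs mirrors clinical reality — lactate and pH
  are deterioration markers in a way a single heart-rate reading is
  not — and keeps on-time discrimination in a realistic 0.9ish band
  rather than saturating at 1.0;
* missingness: independent per cell (MCAR) at per-variable rates by
  default, or state-dependent (`informative_missingness = TRUE`), in
  which sicker hours are measured more often — emulating that
  clinicians order labs when a patient looks worse. Real ICU
  missingness is plausibly informative, so both modes exist and the
  model-ordering benchmark uses the informative one;
* stays log-normal around three days, ages and pre-admission flags for
  exercising the cohort filters.

What the generator does **not** emulate: cross-variable noise
correlation beyond the single latent factor, multi-factor physiology,
charting artefacts (unit mix-ups, duplicated rows), demographic
structure, competing risks (death/discharge are independent of $z$
here), and label noise in event ascertainment. A green test on this
cohort therefore establishes that the implementation learns the
structure it claims to exploit — not that it would attain any
particular performance on hospital data.

`ordering_benchmark_config()` is the regime for comparing variants:
every lab at the top of its realistic missingness range (0.5–0.8),
the scale channel half missing, informative missingness. Under
missingness this heavy the forward-filled series is stale most hours,
which is the failure mode decay imputation targets. Two honest caveats,
both visible in the bundled benchmark: at the event hour itself all
recurrent variants sit near the ceiling (a hazard-driven event is, by
construction, preceded by an extreme latent state that every variant
detects), so on-time *margins* between variants at this cohort size
(roughly 17 positive evaluation points per seed, AUROC standard error
~0.03–0.05) are within sampling noise; the separation between
decay-based and mean-fill models appears at the in-advance horizons and
in pooled model-selection AUROC.

## 6. External-site adaptation

Two mechanisms for a model trained at one hospital and applied at
another: `fit_rescale()`/`apply_rescale()` learns, per variable, the
affine map sending the external *training* portion's median/IQR onto
the internal training median/IQR (robust under heavy missingness; a
zero external IQR degenerates to a pure median shift; medications are
binary and left alone; raw external values are not pre-filtered by the
internal-unit fences, which would be meaningless before units align).
`finetune()` continues optimisation from the checkpoint on a seeded
10/10/80 patient split of the external cohort (fine-tune /
model-selection / validation), at one tenth of the original learning
rate, evaluating only on the 80%. The bundled experiment
(`external_validation()`) simulates a site whose continuous channels
are shifted by 2 units of spread and stretched 2.5-fold, and fine-tunes
*from the rescaled cohort*: rescaling needs no outcome labels, so a
deploying site would always apply it before spending labels on
fine-tuning.

## 7. Numerical choices and degenerate inputs

* Quartiles: type-7 (linear interpolation) everywhere, so independent
  reimplementations agree bit-for-bit.
* AUROC ties: one half, via midranks; AUPRC: tied scores enter as one
  threshold.
* BCE clamps probabilities to $[10^{-12}, 1-10^{-12}]$; the gradient
  uses the logit form and needs no clamping. Non-finite activations
  abort with the timestep index; non-finite losses abort with the
  epoch.
* The ReLU inside the decay has a kink at 0; its subgradient there is
  taken as 0 (gradient checks avoid the kink).
* Degenerate cases with defined behaviour: zero-IQR fences (no-op,
  logged), zero-range scaling (constant 0, warning), all-missing
  first steps and stay-long missing variables (finite by
  construction), empty reconstruction mask (term is 0), a horizon with
  no eligible events (row absent, logged), single-class metric inputs
  (explicit error).
* Determinism: every stochastic step (simulation, splits,
  initialisation, batch order, negative draws, permutations) flows
  from one integer seed; two runs of any stage are bit-identical, and
  manifests hash (configuration, seed) so artifacts are reconstructible
  from their manifest alone. Checkpoints are JSON at full precision;
  a reloaded model reproduces risks to ~1e-12 (decimal round-trip).

## 8. Open design choices

Choices made where more than one defensible design existed, recorded
here as this package's position:

* *Outlier cells, not outlier hours*: the IQR filter blanks the cell
  and keeps the hour, preserving the delta recurrence.
* *Per-patient loss weighting*: weighted BCE is averaged over each
  patient's hours first, then over patients, so long stays do not
  dominate.
* *Negative sampling for horizon metrics*: one time-matched draw per
  control (see §4); alternatives (all control hours, random hours)
  confound stay length with risk.
* *Early stopping on pooled AUROC* rather than event-hour AUROC: far
  more evaluation points, much less selection noise.
* *Imputation fallback*: the GRU-D++ default blends toward the
  hidden-state head; the trainable static fallback and the frozen
  empirical mean remain available as variants.
* *Fine-tuning starts from the rescaled external cohort* (§6).
* *Hidden size and budgets*: `H = 64` default; benchmark harnesses use
  `H = 32`, 30 epochs, patience 8 to fit one CPU.

## 9. Known limitations

* The simple-RNN and plain-GRU baselines share the compiled engine;
  LSTM and tree/boosting baselines are not shipped (no suitable engine
  among the package's dependencies), so the baseline panel is logistic
  regression plus the recurrent family.
* Shapley ranking is sampling-based: with few permutations the noise
  floor on null variables is nonzero; the planted-signal test uses a
  2× dominance margin for that reason.
* The generator's single latent factor makes all informative channels
  mutually redundant; real charts have partially independent organ
  systems, which would likely *increase* the value of good imputation.
* Per-hour risks are not calibrated probabilities; ranking metrics are
  the supported readout.
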