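---
title: "Lognormal movement modelling and risk-factor classification with kinestroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lognormal movement modelling and risk-factor classification with kinestroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinestroke)
```

## The scientific problem

Cerebrovascular risk factors — diabetes, hypertension, hypercholesterolemia,
cardiac disease, obesity, smoking — are accompanied by a gradual
deterioration of psychomotor control. `kinestroke` implements an analysis
pipeline that asks how much of that association can be read off rapid pen
movements recorded on a digitizing tablet: subjects perform a nine-task
battery (reaction strokes, speed/accuracy pointing, stroke sequences,
oscillations, signatures), each movement is reduced to the parameters of a
lognormal neuromotor model, robust per-subject features are aggregated, and
the presence of each risk factor is classified from those features alone.
Performance is summarized as a risk-factor × task matrix of areas under the
ROC curve (AUC).

Because the underlying clinical recordings are not public, the package
ships a synthetic cohort generator that emulates the study design — 120
subjects, the published risk-factor prevalences and co-occurrence pattern,
the task protocols, a 200 Hz / 0.01 mm acquisition chain — so every stage
of the pipeline can be exercised, validated and stress-tested end to end.

## The lognormal model family

The kinematic theory of rapid human movements describes the speed profile
of a ballistic stroke as the impulse response of a chain of neuromuscular
subsystems, which converges to a lognormal in time. One component with
command onset $t_0$, amplitude $D$, log-time delay $\mu$ and log-response
spread $\sigma$ contributes

$$D\,\Lambda(t) = \frac{D}{\sigma\sqrt{2\pi}\,(t-t_0)}
  \exp\!\left(-\frac{(\ln(t-t_0)-\mu)^2}{2\sigma^2}\right), \qquad t > t_0,$$

zero at or before $t_0$, integrating to $D$. Three compositions cover the
battery:

* **Delta-lognormal** (rapid reaching, tasks #2–#5): an agonist pushes and
  an antagonist brakes, both triggered at the same $t_0$:
  $v(t) = D_1\Lambda_1(t) - D_2\Lambda_2(t)$. Net displacement is
  $D_1 - D_2$.
* **Sigma-lognormal** (stroke sequences and signatures, tasks #1, #6, #9):
  a time superposition of strokes, each travelling along a circle arc
  whose direction interpolates from $\theta_s$ to $\theta_e$ by an error
  function in log time — equivalently
  $\phi_i(t) = \theta_{s i} + (\theta_{e i}-\theta_{s i})\,
  P_{\ln\mathcal N(\mu_i,\sigma_i)}(t - t_{0i})$, the lognormal CDF.
* **Omega-lognormal** (oscillations, tasks #7–#8): a one-dimensional
  alternating train of forward and backward components whose counts differ
  by at most one.

`synthesize_trial()` closes the loop back to raw data: the analytic
velocity is integrated on an internal grid at least four times the output
rate (trapezoidal rule), decimated to the 200 Hz sampling grid, and
positions are rounded to the 0.01 mm quantization step — sampling and
quantization applied last, like the digitizer. Time is trial-local; the
stimulus onset is metadata and is never subtracted from the samples, so a
fitted $t_0$ stays directly comparable to a reaction time.

## Parameter extraction

`compute_speed_profile()` differentiates pen-down segments by central
differences and optionally applies a zero-phase 2nd-order Butterworth
low-pass (default cutoff 15 Hz — wide enough for rapid strokes at 200 Hz,
tight enough to suppress quantization noise in real, noisy recordings).
For noiseless synthetic round trips the filter is better switched off;
the tests do so and state it.

`fit_delta_lognormal()` is a three-stage cascade:

1. **Analytic initialization** — onset from backward extrapolation of the
   rising edge, agonist shape from weighted log-time moments, amplitudes
   from net displacement and any terminal negative lobe; plus a
   *deflation* estimate (fit the agonist on the pre-peak region, read the
   antagonist off closed-form moments of the post-peak residual).
2. **Bounded nonlinear least squares** (L-BFGS-B) over all seven
   parameters, multi-started from the deflation estimate and a small grid
   of antagonist variants.
3. **Pattern search** (Hooke–Jeeves) refinement from the best optimum;
   the better of stages 2–3 by RMSE is returned.

Two numerical choices matter and are deliberate:

* **Measurement-domain matching.** The model is not compared to the
  observed profile as an analytic velocity; instead the model's analytic
  *positions* at the sample times are pushed through exactly the same
  finite-difference (and, if used, the same filter) as the data. The
  discretization bias then cancels on both sides. Without this, the
  structured differentiation error at 200 Hz is large enough to move the
  least-squares optimum several percent in $D_1$.
* **A displacement channel in the objective.** The agonist–antagonist
  split is near-degenerate in the velocity channel: wrong splits can fit
  the observed velocity *better* than the truth at the quantization noise
  floor. The cumulative-trapezoid displacement channel is
  quantization-limited rather than differentiation-limited, and weighting
  it by the noise-standard-deviation ratio $\mathrm{rate}/\sqrt{2}$
  restores identifiability (differentiating white position noise of
  variance $\sigma_x^2$ gives velocity noise
  $\sigma_x^2\,\mathrm{rate}^2/2$, while re-integrating returns to
  $\approx \sigma_x^2$). The regime is checked rather than assumed: a
  quick velocity-only pre-fit estimates the actual noise level, and when
  measurement noise dominates quantization the displacement channel is
  switched off — its integral is then a random walk and would bias the
  fit. In the quantization-limited regime a final pattern-search
  refinement runs against a forward model that reproduces the
  digitizer's rounding exactly, whose global minimum sits at the
  generating parameters.
* **A priori amplitude bounds.** The braking burst is smaller than the
  drive for reaching strokes, so the fit constrains $D_1 \le 2.5\,A$ and
  $D_2 \le 1.2\,A$ (with $A$ the observed net displacement); besides
  encoding the physiology, this stops noise-fitting from escaping into
  huge-overlap agonist/antagonist solutions.

The sigma- and omega-lognormal extractors are greedy: locate the most
prominent remaining speed lobe between speed minima, fit one component
(angles from the trajectory tangents at the lobe edges; sign-constrained
along the principal axis for oscillations), subtract, repeat until the SNR
gain drops below 1 dB or the component cap (40) is reached, then jointly
refine when the model is small (≤ 12 components; joint refinement is
quadratic in component count and adds little once lobes are well
separated). The omega extractor enforces $|N-M|\le 1$ by dropping the
weakest surplus component; its oscillation axis is the first principal
axis of the velocity samples (for an oscillation this coincides with the
principal axis of the trace, and the speed-profile interface carries no
positions).

Fit bounds are $\mu \in [-4, 1]$, $\sigma \in [0.05, 1.5]$,
$t_0 \in [0, t_{\text{peak}}]$ — generous envelopes for human rapid
movements; values outside a narrower typical range only warn at
construction, since extraction must be able to represent borderline
movements.

## Validity rules and features

`validate_trial()` applies the protocol's rejection rules: movements too
slow for the task, no stop before the pen lift, no pen lift between
trials, anticipated starts (motion onset before the stimulus — onset
defined as the first sample above 5 % of peak speed sustained ≥ 15 ms, a
standard kinematic onset rule), and an end-to-end amplitude below the
130 mm guiding-sheet minimum for the reaction-stroke tasks. Learning-phase
trials are discarded outright. Only valid trials reach the feature stage.

Per trial, `trial_measures()` computes reaction time, movement duration,
peak speed, time to peak, amplitude, and the flattened model parameters
(for sigma/omega fits: component count and mean $D$, $\mu$, $\sigma$).
Per subject and task, `aggregate_subject()` emits the median and the
unscaled median absolute deviation of each measure — robust location and
spread, insensitive to single outlier trials. The speed/accuracy task
additionally contributes the per-subject slope of movement duration
against the Fitts index of difficulty $\log_2(2D/W)$; the synchronized
oscillation task is split into a paced adaptation segment (first 10 s)
and an unpaced steady-state segment (last 5 s). The exact feature list
(roughly 20 per task) is fixed by the code rather than configurable,
because downstream subset selection makes the classifier robust to the
precise composition.

## Classification and reporting

`auc()` is the Mann–Whitney estimator (ties at half weight) — the
probability of ranking a random affected subject above a random unaffected
one; `roc_curve()` produces the empirical curve whose trapezoidal area
equals it exactly. `loo_posteriors()` yields one held-out probability per
subject via leave-one-subject-out cross-validation, with features
standardized by training-fold statistics only; classifiers are
maximum-likelihood logistic regression and the pooled-covariance LDA Bayes
posterior under the training-fold prevalence prior (with a fixed-ε ridge
retry on singular covariances, flagged in the run metadata).
`select_feature_subset()` is a semi-exhaustive search capped at six
features: univariate-AUC ranking, exhaustive subsets of size ≤ 3 from the
top 12, then beam extension (width 10) to size ≤ 6, deterministic
tie-breaks. `build_auc_matrix()` assembles the risk-factor × task matrix;
selection can run inside every fold (`nested`, unbiased but expensive),
once on all subjects (`pooled`, the likely original protocol), or be
fixed (`none`). Both classifier kinds are emitted; the package never
silently reports the better one.

Medians of the published summary table are recomputed from its 42 cells
with the midpoint convention and rounded half-away-from-zero to two
decimals; threshold fractions use the floor of the percentage — the only
rounding rule consistent with the published 83 % / 35 % figures.

## The synthetic cohort

`generate_cohort()` reproduces the study composition exactly: 120
subjects (ages 25–85, 68 women / 52 men), 57 risk-free, factor totals
DM 15 / OB 10 / HT 40 / HC 28 / CD 24 / CS 13 distributed over a
co-occurrence pattern of 25/18/12/7/1 subjects with 1–5 factors (the
totals are mutually consistent: $\sum_f n_f = \sum_k k\,n^{(k)} = 130$).
Latent per-subject baselines are population conventions, not published
values: $\mu_1 \sim \mathcal N(-1.6, 0.15)$ with a mild age slowing
(+0.004 per year), $\sigma_1 \sim \mathcal N(0.35, 0.05)$ truncated below,
reaction latency $t_0 \sim \mathcal N(0.22, 0.03)$ s, and a per-subject
amplitude scale. The foreperiod generator is exponential with rate
0.4 s⁻¹, redrawn outside (0, 10] — the published protocol fixes only the
flat-hazard property and the bounds.

The mapping from risk factors to movement parameters is *unknown* — it is
the research question of the original study — so `effect_config()` is an
explicit fiction: per factor, an additive shift on $\mu_1$, a
multiplicative factor on $\sigma_1$, an additive shift on the reaction
latency, and a multiplier on within-subject trial spread, combining
multiplicatively across co-occurring factors. The shipped default is
sized so the simulated pipeline lands in the 0.6–0.9 AUC range the real
battery reports; `strong_dm_effects()` plants a large diabetes-only
effect (≈ 2 between-subject SDs on the latency) for sensitivity studies.
Passing tests on this cohort demonstrates that the pipeline recovers
planted structure and invents none on null data — it says nothing about
the biological truth of any risk-factor/movement association, and the
generator deliberately omits features of real data (pen pressure,
fatigue drift, handedness mirroring, heavy-tailed trial outliers).

Sessions follow the protocols: SRT/CRT sessions keep recording until the
required number of *valid* trials (15 / 30) has accumulated, as the
acquisition software did; the speed/accuracy task runs its 4 × 4 × 2
factorial; triangles 2 × 3 × 2; oscillations 10 s at maximal speed or
metronome-paced with a 5 s unpaced continuation; signatures come from a
fixed per-subject seeded template redrawn with small jitter. A
configurable fraction of reaction trials violates the rules (anticipated
starts, short amplitudes) to exercise the validator. One master seed
fixes the roster, every latent parameter and every sample.

## Problem sizes used by the shipped studies

The package's own validation studies (tests and the worked examples) use
deliberately chosen reduced sizes: recovery studies fit 200 synthetic
reaching trials; sensitivity and null-calibration studies use 60-subject
cohorts with 20 valid trials of the visual SRT per subject and classical
measures only (no per-trial model fit), 20 replicate cohorts per
condition, LDA on a fixed documented feature triple
(`med_reaction_time`, `mad_reaction_time`, `med_movement_duration`).
These sizes give stable Monte-Carlo estimates while keeping a full run on
one core in minutes.

## Known limitations

* **Leave-one-out AUC is pessimistically biased on null data.** With
  n = 60 and no true signal, out-of-fold probabilities are anti-correlated
  with the held-out label (removing a subject shifts the training
  prevalence and the fitted direction against it); measured means fall
  around 0.35–0.46 depending on classifier, subset size and prevalence
  — not 0.5. Pooled-selection runs are biased the other way (optimism).
  The replicate studies report what the estimator actually produces;
  interpreting a LOO AUC near 0.5 as "chance" is only safe when feature
  dimension is small relative to n.
* The delta-lognormal agonist/antagonist split is intrinsically
  ill-conditioned when the antagonist closely shadows the agonist
  (small $\mu_2-\mu_1$, $\sigma_2 \approx \sigma_1$). At 200 Hz /
  0.01 mm this is not merely an optimization nuisance: for a
  non-negligible fraction of such configurations, parameter sets several
  percent apart in $D_1$ reproduce the *identical* quantized recording,
  so no extractor can separate them. $t_0$, $\mu_1$ and $\sigma_1$
  remain sharply identified throughout; measurement noise widens the
  $D_1$/$D_2$ uncertainty long before it affects them.
* The signature archetype is a stylized stroke pattern, not a model of
  any individual's signature; signature verification is out of scope.
* Oscillation extraction assumes a dominant movement axis; freely curved
  oscillations would need the full sigma-lognormal treatment.

## A worked example

```{r example, eval = FALSE}
library(kinestroke)

# one synthetic reaching trial and its fit
p   <- delta_lognormal_params(t0 = 0.05, D1 = 150, mu1 = -1.6, sigma1 = 0.35,
                              D2 = 30, mu2 = -1.3, sigma2 = 0.45)
rec <- synthesize_trial(p, sampling_spec(rate = 200, duration = 1.2))
fit <- fit_delta_lognormal(compute_speed_profile(rec, smooth = FALSE))
fit$params$agonist$D      # ~150 mm
fit$snr_db                # > 40 dB

# the published summary table, recomputed from its cells
summarize_auc_matrix(auc_table_fixture())

# a small end-to-end run
res <- run_pipeline(pipeline_config(
  n_subjects = 60, tasks = "2", n_trials = list("2" = 20),
  effects = strong_dm_effects(), fit = "none", kinds = "lda",
  selection = "none",
  fixed_subset = c("med_reaction_time", "mad_reaction_time",
                   "med_movement_duration"),
  seed = 1))
res$auc_matrices$lda["DM", "2"]   # well above chance
```
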