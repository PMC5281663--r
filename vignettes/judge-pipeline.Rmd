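---
title: "Breath classification with Tucker3 compression and a gated judge ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath classification with Tucker3 compression and a gated judge ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and its model

A temperature-modulated metal-oxide electronic nose records, for each
breath sample, the conductivity of three sensors while their
micro-hotplates are cycled between 260 and 340 °C in 32 evenly spaced
steps and back (64 temperature values per cycle), over 36 cycles. One
measurement is therefore a 3-way array
\(X \in \mathbb{R}^{64 \times 36 \times 3}\) of strictly positive
conductivities. Redox reactions of the volatile organic compounds (VOCs)
in the breath modulate the conductivity differently at different
temperatures and on different sensor coatings, so a disease-specific VOC
mixture should leave a low-complexity, smooth imprint across the
(temperature, cycle, sensor) axes. That assumption — class information
lives in a low multilinear-rank component of the array — is what the
whole pipeline is built around.

`nosejudge` implements the pipeline in four stages, each fitted strictly
inside the training part of a cross-validation fold:

1. **Preprocessing.** One of five scaling options (`none`,
   `baseline_ratio`, `log_baseline_ratio`, `per_sensor_zscore`,
   `per_measurement_minmax`). The default is `log_baseline_ratio`: each
   sensor trace is divided by that sensor's mean conductivity over the
   first cycle and log-transformed. Log-conductance ratios are the usual
   response measure for metal-oxide sensors, and the ratio cancels any
   per-measurement or per-device multiplicative level — including the
   simulated device factors. Note that `baseline_ratio` is idempotent
   (after one application the cycle-0 mean is exactly 1) but
   `log_baseline_ratio` is not: a second application would see
   non-positive values and is rejected.
2. **Tucker3 compression.** The preprocessed arrays are compressed with a
   Tucker3 decomposition,
   \(X \approx G \times_1 A \times_2 B \times_3 C\), with orthonormal
   factor matrices per mode and a small core \(G\). Factors are fitted
   once per training fold on the *concatenated* training tensors
   (leading eigenvectors of each mode's pooled scatter matrix, refined by
   alternating sweeps); held-out tensors are only ever projected onto
   them. Vectorising the projected core gives each patient a feature
   vector of length \(r_1 r_2 r_3\).
3. **Candidate networks.** Small one-hidden-layer perceptrons with tanh
   activations on the hidden layer and the single output, trained on
   labels coded −1/+1 by deterministic full-batch gradient descent on the
   squared error. The bounded output is a *predictive value* in
   \([-1, 1]\) whose natural decision threshold is 0.00.
4. **The judge ensemble.** One gating network splits samples into a
   positive and a negative group (gate output ≥ 0 routes to the positive
   branch, ties included); each group is scored by a committee of three
   distinct networks whose outputs are averaged. The best
   (gate, committee, committee) assembly is found by exhaustive
   brute-force enumeration over a trained candidate pool, scored by the
   mean inner-fold Matthews correlation coefficient (MCC) of the
   assembled judge.

Validation is a double (nested) cross-validation: the outer loop
(default 10 stratified folds) estimates generalisation to future breath
samples; the inner loop (default 5 stratified folds) performs *all*
model selection — scaling choice, Tucker ranks, and the brute-force
judge assembly. Pooled out-of-fold predictive values are thresholded at
0.00 and summarised by sensitivity, specificity, accuracy, MCC, a
tie-grouped ROC curve with trapezoidal AUC, and stratified percentile
bootstrap confidence intervals.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| Tucker ranks \((r_1, r_2, r_3)\) | (4, 3, 2) → 24 features | feature count must stay small against cohorts of ~128 patients; the grid can include (2,2,1) and (6,4,3) |
| scaling search | `log_baseline_ratio` | cancels multiplicative device/measurement level; the other four options are available in `pipeline_config()` |
| hidden units | {4, 8} | 24 inputs and ~100 training samples cannot support wider nets |
| net seeds | {1, 2} | two deterministic initialisations per width diversify the pool |
| epochs / learning rate (pipeline) | 800 / 0.01 | full-batch descent on ≤ ~115 samples has converged long before 800 epochs at this step size; `train_mlp()` itself defaults to 2000 epochs for standalone use |
| enumeration bound `m` | 8 | committees come from the top-`m` pool members by individual inner score; the search is then exhaustive over pool × \(\binom{m}{3}^2\) assemblies |
| outer / inner folds | 10 / 5 | conventional nested-CV sizes; stratified, seeded |
| threshold | 0.00 | the natural boundary of the tanh output; ties count as positive |
| bootstrap | B = 500–1000, 95% percentile | stratified by class; degenerate resamples are redrawn |

Every stochastic choice — fold assignment, weight initialisation,
simulation, bootstrap — draws its seed from one master seed through
`derive_seed()`, so a whole analysis is a pure function of
(data, configuration, master seed).

## What the synthetic generator emulates — and what it does not

No breath measurements are distributed with the package, so
`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes:

* a shared smooth positive baseline surface per sensor (low-order trends
  in temperature step and cycle, distinct sensor levels);
* class-dependent perturbations of configurable multilinear rank
  (default (1,1,1)): the classes share smooth factor matrices and differ
  only in core coefficients, so the difference between any two class
  templates has multilinear rank at most the configured rank — the
  structure Tucker3 is matched to. The perturbations share one scale,
  chosen so the largest peaks at `amplitude` times the mean baseline
  conductivity; `amplitude = 0` makes the label independent of the data
  by construction;
* per-device multiplicative factors for the five serials
  (259, 309, 315, 362, 379), log-normal with `device_sdlog = 0.1`;
  serial allocation per class follows the reported cohort proportions by
  deterministic largest-remainder apportionment;
* element-wise multiplicative log-normal noise, mean-corrected, with
  coefficient of variation `noise_cv = 0.05` — relative errors dominate
  in metal-oxide sensors and conductances stay positive;
* metadata (age, sex, food intake, smoking, pack-years, stage) sampled
  per class from distributions approximating the reported baseline
  tables. The sources disagree on a few counts (e.g. the HNSCC food
  intake row); the defaults are deliberately loose, and the classifier
  never sees metadata.

The defaults — class sizes 100/40/28, `amplitude = 0.15` (three times
the noise CV), rank-(1,1,1) signatures — are the package's fixed study
conditions. The generator does **not** simulate adsorption kinetics,
specific VOC chemistry, sensor drift between sessions, humidity or diet
effects, or any overlap between disease signatures beyond what the
amplitude encodes. Passing tests on these cohorts therefore show that
the pipeline recovers the kind of structure it is designed for and stays
honest under a null — not that real breath data are this separable. The
real between-device and between-session variances are unknown; both are
exposed in the configuration rather than claimed realistic.

## Numerical choices

* **HOSVD/HOOI.** Factors start as leading left singular vectors of each
  unfolding; alternating sweeps stop when the relative-fit improvement
  drops below `tol = 1e-7` (tests tighten this) or after
  `max_iter = 200` sweeps; non-convergence is flagged on the returned
  model, not an error. Each factor column's largest-magnitude entry is
  made positive, so results do not depend on the SVD backend's sign
  conventions. The fit never falls below the HOSVD initialisation.
* **Group compression.** Whether the vendor software compresses
  per-measurement or per-training-set is undocumented; the package fits
  one set of factors per training fold (pooled scatter matrices) so that
  held-out data can never influence factor estimation. The
  per-measurement alternative would decompose each tensor separately and
  use its core as features; it is intentionally not implemented, to keep
  a single well-audited path.
* **Feature standardisation.** Compressed features are z-scored with
  training-fold statistics before network training (zero-variance
  columns are left unscaled); tanh units otherwise saturate on the raw
  core scales.
* **Ties and degeneracies.** Gate output exactly 0 routes positive;
  predictive value exactly 0.00 classifies positive; MCC is 0 whenever a
  confusion margin vanishes; brute-force score ties break
  lexicographically by provenance order, making selection deterministic.
* **All 36 cycles are kept.** Whether early cycles are warm-up that the
  vendor discards is unknown; `baseline_ratio` referencing cycle 0
  absorbs most of any warm-up level shift.
* **Gated inference.** The judge applies its gate at prediction time
  (the same rule used during selection). The alternative reading — a
  train-time partition of the training data with committees fitted per
  partition — is noted but not implemented.

## Problem sizes used by the test suite

Unit tests run on reduced tensors and cohorts (e.g. 20×15×3 arrays,
cohorts of 24–45 patients, 2–4 outer folds, 80–300 epochs) chosen so the
whole suite exercises every code path at interactive speed. The
end-to-end statistical checks use the full study geometry — 128 patients
(100 vs 28), 10 outer × 5 inner folds — for the null-calibration (five
master seeds, 99% binomial band around the majority rate) and
signal-recovery (accuracy ≥ 0.85, AUC ≥ 0.90 at the default amplitude)
properties, and byte-level determinism of two complete
simulate-and-analyse runs under one master seed.

## Known limitations

* The three pairwise comparisons are reported separately, without
  multiplicity adjustment — matching the reporting convention the
  package reproduces.
* No multi-class (3-way) classification; the judge is a binary machine.
* MCC on very small inner folds is noisy; with the default 5 inner
  folds and ~23 test samples per fold this is tolerable, but
  single-digit inner-fold sizes will make the brute-force selection
  unstable.
* The bootstrap is percentile-only; BCa intervals are out of scope.
* Printed p-values in clinical baseline tables often come from
  software-specific test variants; `fisher_exact_2x2()` implements the
  probability-method two-sided enumeration, which can differ in the
  third decimal from other conventions.
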