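---
title: "Methods: feature-space augmentation for e-nose signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-space augmentation for e-nose signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enoseaug)
```

## Data model

A trial is one exposure of a metal-oxide sensor array to a volatile
sample. Each sensor contributes the first 80 samples (1 Hz) of its rising
voltage response; the per-sensor series are concatenated in a fixed sensor
order into one feature vector of length `S * 80` (240 features for three
sensors). Only the rise phase enters the feature vector — the purge phase
that follows an exposure carries no class signal and is never stored.
Class labels are small integers (`"1"`..`"C"`); a dataset bundles the
trial-by-feature voltage matrix, labels, per-trial identifiers, a
synthetic flag and the sensor layout, and every function validates
finiteness and shape on construction.

## The augmentation methods

**Interpolation–extrapolation** (the method this package is built around).
Each synthetic vector is `x_i + alpha * (x_j - x_i)` where the anchor
`x_i` is uniform over the training trials, the partner `x_j` is uniform
over the anchor's `k` same-class nearest neighbours (Euclidean distance on
the raw features, ties broken toward the lower trial index), and
`alpha ~ Uniform(c1, c2)`. Defaults are `k = 3` and `(c1, c2) = (-2, 3)`.
Restricting partners to same-class neighbours keeps augmentation local and
label-preserving; bounds wider than `[0, 1]` push synthetic points beyond
the segment joining the parents, which in the time domain yields both
amplitude changes and lead/lag deformation of the curves. The bounds are
alternatively set through a half-width `cv` about 0.5
(`cv_to_bounds()`): `cv = 0.5` is pure interpolation, larger values mix in
extrapolation.

**SMOTE** is the exact special case `(c1, c2) = (0, 1)`. The two samplers
share one draw protocol, so `augment_smote()` and
`augment_interp_extrap()` with unit bounds are bit-identical under the
same seed; the test suite verifies the reduction against an independent
oracle that recovers each sample's `alpha` by projecting onto the
parent-difference direction.

**Gaussian noise** adds i.i.d. `N(0, sigma^2)` per component to a
uniformly drawn parent (`sigma = 0.05` V by default — a few percent of the
nominal 0–3 V signal range).

**Signal stretching** simulates a slower sensor response. For each sensor
segment the first `m = round(n / (1 + alpha))` samples (`alpha = 0.1`,
so `m = 73` of `n = 80`) are linearly resampled onto the full `n`
positions. Two prefix rules are plausible for this operation —
`m = round(n / (1 + alpha))`, which shortens the prefix, and
`m = round(n * (1 + alpha))`, which lengthens it; only the first is
consistent with a stretch factor below one producing a *reduced* prefix,
so it is the default, and the second is available behind the
`lengthen_prefix` flag (implemented as upsample-to-`m`, keep the first
`n`).
Stretching is applied per sensor segment: a stretch across segment
boundaries would blend unrelated channels. The combined
noise-and-stretch method draws `T` parents and emits one noise and one
stretched copy each (`N = 2T`).

All methods preserve the parent label, emit exactly the requested count,
never mutate the input dataset, record their parents in a provenance
table, and are bit-reproducible under a fixed seed. Single-member training
classes are a hard error for neighbour-based methods rather than a silent
fallback.

## Classifiers

Four families share one train/predict/score contract:

* **ANN-nl-nu** — fully connected network, `nl` hidden tanh layers of `nu`
  units (default 3 × 50), softmax over the classes, mean cross-entropy
  loss, full-batch Adam (`lr = 0.01`, at most 400 epochs), early stopping
  with patience 40 on a stratified 15 % slice of the training pool, with
  best-weight restoration. The validation slice is cut from the
  *augmented* pool, so synthetic trials participate in both fitting and
  stopping. Inputs are internally mapped per feature onto `[-1, 1]`
  (min–max, fitted on the training pool) — the standard conditioning for
  tanh networks, without which gradient flow through three saturating
  layers is unreliable on raw voltages. This internal conditioning is
  part of the optimizer, not a modelling choice; the user-facing
  `standardize` flag (z-scoring for any classifier family) stays off by
  default. Argmax ties break toward the lower class index.
* **MSVM** — one-vs-one linear-kernel SVM ensemble with majority voting
  (`e1071`). Deterministic: refitting on the same data gives the same
  model regardless of seed.
* **RF** — random forest (`randomForest`), 100 trees, Gini splits,
  bootstrap sampling; stochastic across seeds.
* **PCA-nv-MSVM** — projection onto the leading `nv` principal components
  (centred on the training mean, no scaling or whitening, never refit on
  test data), then the MSVM in the reduced space.

Accuracy is `100 * trace / total` of the true-by-predicted confusion
matrix over the full class inventory; the two are computed together so
they cannot disagree.

## The evaluation harness

An experiment plan fixes the data source, split sizes (default 7 train +
5 test from 12 trials per class), classifiers, augmentation settings, the
augmentation-size grid (default 0/100/500/2000), and repeats (default 10).
The master seed spawns labelled substreams for the data draw, the split,
each repeat's augmentation and each repeat's training, so any cell of a
sweep can be recomputed in isolation and a whole run is deterministic.

The split is drawn once per experiment; the same untouched test set serves
every condition. Test trials are never augmented, and a provenance-based
leakage guard (`assert_no_leakage()`) runs on every augmentation call the
harness makes.

By default a **fresh synthetic pool is drawn for every repeat**
(`fresh_draws = TRUE`): repeat-to-repeat spread then reflects both
training and augmentation randomness. The alternative — one frozen pool
per condition — is a flag. The choice matters for the deterministic MSVM:
with fresh draws its accuracy varies with the pool, while on a frozen pool
repeated MSVM trainings are identical and their SD is exactly zero. The
package's stability claims for MSVM are therefore stated (and tested)
under `fresh_draws = FALSE`.

`cv_sweep()` scans the bound half-width over a positive grid (500
synthetic trials per cell by default) and smooths the accuracy series with
a forward moving average over each value and its 10 successors, truncated
at the tail. `method_comparison()` fills a methods-by-sizes mean-accuracy
table for all five methods under shared settings (`k = 3`,
`sigma = 0.05`, `stretch_alpha = 0.1`, bounds `(-2, 3)`).

## The synthetic signal generator

Real rise-phase responses are smooth, concave, saturating curves that
differ across classes in amplitude and rise speed. The generator emulates
exactly that: per sensor `s` and class `c`,

`v(t) = B[s] + A[c,s] * (1 + a) * (1 - exp(-t / (tau[c,s] * (1 + b)))) + e(t)`

with `a ~ N(0, sd_amp^2)` and `b ~ N(0, sd_tau^2)` drawn once per trial
and sensor (class-preserving trial-to-trial variability) and
`e(t) ~ N(0, sd_noise^2)` i.i.d. per sample. Class templates spread a
single base amplitude/time-constant row across classes along an equispaced
class axis scaled by one separability knob `delta`; `delta = 0` collapses
all classes onto one template. Volt scales are nominal (0–3 V), read off
typical sensor traces rather than calibrated.

Three presets are frozen in the packaged `scenarios.yaml`:

* `separable` (`delta = 0.6`, low jitter) — every classifier family
  should solve it outright;
* `overlapping` (`delta = 0.25`, `sd_amp = 0.08`, `sd_tau = 0.10`,
  `sd_noise = 0.03` V) — calibrated once by simulation so that the
  baseline ANN-3-50 with the 7/5 split lands in the 55–80 % band over ten
  seeds, then frozen. This is the regime where augmentation has room to
  act, and the preset used by the acceptance script;
* `chance` (`delta = 0`) — accuracy concentrates at `100/C` %.

What the generator does **not** emulate: baseline drift, purge-phase
tails, humidity/temperature covariates, heteroscedastic or correlated
noise, and any adsorption-kinetics detail of real oxide surfaces. Passing
tests on this generator show that the pipeline's algebra, protocol and
directional behaviour are right — not that any particular accuracy will
transfer to a given instrument.

## Numerical and design notes

* `alpha` is drawn from a continuous uniform; endpoint inclusion is
  measure-zero and not distinguished.
* kNN distances use raw (unstandardized) features; ties break on the
  lower index for determinism.
* Synthetic trials are never re-used as anchors or neighbours within one
  call: augmentation is single-generation.
* Accuracy on a 30-trial test set moves in steps of 3.33 points; with ten
  repeats, mean differences of a few points between augmentation sizes
  are at the edge of resolution, and on an easy split (high baseline) the
  mean gain from augmentation can be absent even though the SD reduction
  persists. The acceptance script reports both the mean accuracies and
  the SDs so this can be inspected per run.
* Test-suite and acceptance problem sizes — 10,000 synthetic samples for
  the geometry checks, 20 generator repeats for the chance calibration,
  10 trainings per benchmark condition — were chosen as the smallest
  sizes at which the checked quantities are stable.
* CSV persistence writes full `write.csv` precision (~15 significant
  digits); the round-trip tolerance contract is 1e-12 relative.

## Known limitations

* The ANN trainer is a plain full-batch Adam network sized for hundreds
  to a few thousands of rows; it makes no attempt at GPU scale,
  mini-batching or hyperparameter search.
* The loader for external raw-instrument formats is an adapter hook
  (`register_dataset_adapter()`), not a parser: on-disk dialects of
  deposited e-nose archives vary and are best handled by a user-supplied
  reader returning an `enose_dataset`.
* `pca_msvm` probability outputs are not provided; only the ANN exposes
  calibrated-ish class probabilities.
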