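---
title: "Methods: statistical-feature GP/KNN spike detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical-feature GP/KNN spike detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The detection problem

Interictal spikes — brief (tens of milliseconds) sharp transients between
seizures — are the first landmark clinicians look for when localising an
epileptic focus in MEG. A whole-head system records ~300 sensors at 1000 Hz
for sessions of many minutes, so manual marking is slow and subjective.
`spikegp` implements a patient-independent detector that works per brain
region (26 gradiometer channels; 24 for the occipital regions) in three
stages:

1. **Preprocessing.** Each channel is cut into 100 ms windows with 50%
   overlap, each window is median-smoothed, and eight statistics are
   extracted per window: max, min, mean, standard deviation, median,
   interquartile range, kurtosis, skewness (`X1..X8`).
2. **Feature generation.** Genetic programming (GP) evolves a single scalar
   formula over `X1..X8`. An individual is an expression tree over
   `{plus, minus, times, sin, cos, log}`; its fitness is the error rate of a
   one-dimensional K-nearest-neighbour (KNN) classifier that uses the
   formula's outputs on a balanced *reference* group as reference points and
   a balanced *validation* group as queries. The search is elitist
   (mu + lambda), 25 individuals, 100 generations, trees capped at 25
   levels.
3. **Classification.** The best formula scores every window of every
   channel; each channel's scalar is classified by KNN (k = 100) against
   the *same* reference points, and a window is called a spike when the
   spike votes form a strict majority of the region's channels
   (> 13 of 26, > 12 of 24).

The package also ships a synthetic simulator so that the complete pipeline
is testable without clinical recordings, which are not publicly
distributable.

# Definitions that are deliberately nonstandard

The window statistics follow the defining equations of the method rather
than the common estimators:

* standard deviation uses the 1/(N−1) normalisation, and — unusually —
  **kurtosis and skewness do too**:
  kurtosis = Σ(Xᵢ−μ)⁴ / ((N−1)·σ⁴) and
  skewness = Σ(Xᵢ−μ)³ / ((N−1)·σ³).
  A Gaussian window therefore has kurtosis near 3·N/(N−1), and these values
  differ from `e1071::kurtosis()`-style moment estimators. The test suite
  checks them against an independent direct-summation oracle.
* quartiles are medians of the **exclusive halves** of the sorted window
  (the middle point is dropped from both halves when N is odd), with no
  interpolation; IQR = Q3 − Q1.
* a zero-variance window would make both shape statistics 0/0; they are
  defined as 0 and the window flagged degenerate, so downstream formula
  evaluation never sees a non-finite input.

# Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `window_ms` | 100 | window length; at 1000 Hz exactly N = 100 samples, matching the bulk of spike durations |
| `overlap_fraction` | 0.5 | consecutive windows share half their samples |
| `median_filter_order` | 5 | kernel of the per-window running median, edge-replicated |
| `population_size` / `n_generations` | 25 / 100 | GP search budget |
| `max_tree_level` | 25 | depth cap enforced by reject-and-resample |
| `p_crossover_init` / `p_mutation_init` | 0.90 / 0.10 | initial operator probabilities |
| `adaptation_step` / `p_mutation_cap` | 0.05 / 0.40 | adaptive schedule (below) |
| `knn_k` | 100 | neighbours in the classification stage |
| `group_max_per_class` | 200 | cap on segments per class per fitness group |

Choices the method's published description leaves open, and how this
package resolves them:

* **Median filter order and boundary.** The smoothing filter is named but
  its kernel is not. Order 5 removes one- and two-sample artifacts while
  leaving 20 ms transients essentially intact; edges are handled by
  replicating the first/last sample so output length equals input length.
* **Window labelling.** Experts mark spike (start, end) intervals; how a
  100 ms window inherits a label is unstated. A window is a spike when it
  overlaps an annotated interval by at least half the window. With 50%
  window overlap this guarantees every spike of ≥ 50 ms duration labels at
  least one window positive; it also means spikes shorter than half a
  window never produce a positive window (see Limitations).
* **Adaptive operator probabilities.** Only the initial 90%/10% values and
  the fact that they adapt per generation are given. The package's rule:
  a generation with no improvement in best fitness moves 5 points from
  crossover to mutation (mutation capped at 40%); any improvement resets
  both to their initial values. The rule is monotone, simple and testable,
  and the probabilities always sum to 1.
* **Initialisation.** Ramped half-and-half over depths 2–6, the community
  default for diverse initial GP populations.
* **Parent selection.** Tournament of size 2; selection pressure mostly
  comes from the elitist survivor step (best 25 of parents ∪ offspring).
* **Terminals.** Feature indices only, no numeric constants: the published
  parameter table lists no constant set and the example evolved formulas
  use features only.
* **Fitness KNN's k.** Unstated (only the classification stage fixes
  k = 100); the package uses the same k in both places, clamped to the
  reference-group size.
* **Protected operators.** `log x` is `log|x|`, and 0 within 1e−12 of
  zero. Deep `times` chains can still overflow double precision, so any
  non-finite value at the tree root is mapped to 0: formula outputs are
  finite by contract.
* **24-channel voting.** The strict threshold is only published for 26
  channels (> 13); the occipital regions use the same strict-majority
  semantics, > 12 of 24.
* **Even-k vote ties.** k = 100 is even; a 50–50 vote is resolved by the
  label of the single nearest reference — deterministic and data-driven
  rather than a fixed class bias. Reference points at exactly equal
  distance are ordered by their insertion order, for reproducibility.
* **Evaluation unit.** Per window, matching the per-segment classifier
  outputs; merging adjacent positive windows into events is offered only
  as human-readable post-processing.
* **Sensitivity/specificity.** The standard clinical definitions,
  100·TP/(TP+FN) and 100·TN/(TN+FP); zero-denominator ratios are reported
  as not-applicable rather than silently 0.

# The synthetic generator

`simulate_recording()` emulates the target acquisition: 1000 Hz, 26 (or 24)
channels, background band-limited to 1–50 Hz (Fourier-mask filtering of
white Gaussian noise, unit RMS per channel), and Poisson-placed,
non-overlapping spike events. Each event is a Mexican-hat (second
derivative of a Gaussian) transient — a sharp biphasic peak, zero mean,
unit peak — with duration drawn from a normal(70 ms, 25 ms) truncated to
[20, 150] ms, scaled by `snr` (peak over background RMS, default 5) and by
per-channel gains from a positive-truncated Normal(1, 0.2), then added to
*all* channels of the region simultaneously. The coherent cross-channel
insertion with jittered gains is what justifies regional majority voting.
The default rate of 6 events/min sits within the clinically reported
interictal range and gives a 300 s recording enough positive windows for
stable rate estimates.

What the generator does **not** model: 1/f background structure, ocular and
cardiac artifacts, sensor drift, focal (sub-regional) field patterns, and
ictal dynamics. Passing tests on simulated data therefore demonstrate the
pipeline's mechanics and its behaviour under controlled separation, not
clinical-grade performance; the published clinical accuracy figures cannot
be reproduced without the original recordings.

# Study conditions used by the tests and the acceptance script

The end-to-end runs use 8 simulated training patients (40 s each; four
become KNN reference points, four validation inputs, assigned at patient
level so no patient contributes to both) and 4 held-out patients of 75 s
each — 300 s of evaluation data per run — at snr 5. Fitness groups are
balanced by seeded undersampling and capped at 200 segments per class,
reflecting that the wrapper fitness only needs a small balanced sample.
These sizes keep a full 25 × 100 search plus classification of ~6000
regional windows to about a minute while leaving hundreds of events across
the evaluation runs.

# Numerical and degenerate-case policy

* 0-based sample indices and half-open `[start, end)` intervals throughout.
* Window starts are `0, step, 2·step, …` with `step = N·(1−overlap)`;
  a trailing partial window is discarded
  (`floor((L−N)/step) + 1` windows).
* A signal shorter than one window raises an error rather than returning
  an empty result.
* `k` is clamped to the reference-set size with a warning, so toy fixtures
  run unchanged.
* Crossover/mutation offspring deeper than 25 levels are rejected and
  resampled up to 10 times, then the parent passes through unchanged —
  population size and the depth cap hold unconditionally.
* All randomness flows through R's RNG; every simulator, GP and pipeline
  entry point accepts a seed, and a pipeline rerun from its manifest seed
  is bit-identical.

# Behaviour under null (placebo) conditions

A methodological point worth stating explicitly: on pure noise with
randomly placed "spike" annotations, the detector's decisions are
independent of the labels (sensitivity equals 100 − specificity up to
binomial error), but the regional positive *rate* is not 50%. Two effects
drive it down. First, the strict majority `> 13` of 26 is asymmetric at an
even channel count: even a perfectly calibrated per-channel rate of 0.5
yields a regional rate of P(Binomial(26, 0.5) > 13) ≈ 42%. Second, wrapper
selection under null labels preferentially finds formulas that compress the
(clustered, hence lower-effective-dimension) placebo-positive group into
narrow scalar regions, leaving per-channel rates of roughly 0.40–0.48 on
fresh noise, which the vote then amplifies away from one half roughly
fourfold. Observed regional rates on null runs scatter around ~25%. This
is a property of wrapper-selected majority-vote detectors, not a defect of
the implementation; the corresponding label-independence check is the
meaningful null test.

# Limitations

* Events shorter than half a window (< 50 ms at the defaults) never
  receive a positive ground-truth window, yet often classify positive —
  they surface as false positives in per-window evaluation. This bounds
  specificity slightly below 100% even at high snr.
* The evolved formula is a single scalar; channel-specific or multivariate
  decision rules are out of scope.
* Reference points are global (patient-independent) by design; no
  per-patient calibration is attempted.
* Bloat is controlled only by the depth cap; evolved formulas can be large
  (and slow to evaluate) even when an equivalent small formula exists.
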