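# spikegp

Patient-independent detection of interictal spikes in multichannel MEG
recordings, built from three stages:

1. **Preprocessing** — every channel is segmented into 100 ms windows with
   50% overlap, median-smoothed, and summarised by eight statistics per
   window: `X1` max, `X2` min, `X3` mean μ, `X4` standard deviation σ,
   `X5` median, `X6` interquartile range, `X7` kurtosis, `X8` skewness,
   with

   μ = (1/N) Σ Xᵢ,  σ = √( Σ(Xᵢ−μ)² / (N−1) ),
   kurtosis = Σ(Xᵢ−μ)⁴ / ((N−1)·σ⁴),  skewness = Σ(Xᵢ−μ)³ / ((N−1)·σ³),

   and quartiles as medians of the exclusive halves of the sorted window.
2. **GP feature generation** — genetic programming evolves a scalar
   formula over `X1..X8` (function set plus/minus/times/sin/cos/log,
   25 individuals, 100 generations, 25-level depth cap, adaptive
   crossover/mutation probabilities starting at 90%/10%). Fitness is the
   error rate of a 1-D K-nearest-neighbour classifier: reference points are
   the formula's outputs on a balanced reference group, queries a balanced
   validation group; lower is better, survivors are the fittest 25 of
   parents and children.
3. **Classification** — the best formula scores every window of every
   channel of a brain region; each channel's scalar is classified by KNN
   (k = 100) against the same reference points, and the region's window is
   called a spike when spike votes form a strict majority (> 13 of 26
   channels, > 12 of 24). Performance is reported as sensitivity
   100·TP/(TP+FN) and specificity 100·TN/(TN+FP) over windows.

Clinical MEG recordings of this kind are not publicly distributable, so the
package includes a synthetic generator (`simulate_recording()`): 1–50 Hz
band-limited unit-RMS background plus Mexican-hat transients of 20–150 ms,
inserted coherently across a region's channels with jittered per-channel
gains. It is aimed at biomedical-signal researchers who want a fully
testable, reproducible reference implementation of this detector family.

## Worked example

```r
library(spikegp)

# eight simulated training patients, two held out
train <- setNames(lapply(1:8, function(i)
  simulate_recording(sim_config(duration_s = 30, snr = 5, rng_seed = i))),
  paste0("train", 1:8))
holdout <- setNames(lapply(9:10, function(i)
  simulate_recording(sim_config(duration_s = 60, snr = 5, rng_seed = i))),
  paste0("holdout", 9:10))

cfg <- experiment_config(gp = gp_config(rng_seed = 42), balance_seed = 1)
res <- run_pipeline(train, holdout, cfg, seed = 1)

res$formula
#> <gp_tree> depth 10 size 41
#>   (plus (plus X4 X4) (plus (minus (plus (minus (plus X4 (minus (log (log X1))
#>   (minus X1 X8))) (minus X5 (plus (plus X4 X4) (plus X4 (minus X1 X8)))))
#>   (minus X1 X8)) (minus (minus X1 X8) (plus X4 X4))) (minus X1 X8)))
res$evaluation$sensitivity
#> [1] 100
res$evaluation$specificity
#> [1] 99.53782
res$evaluation$counts
#>   TP   FP   TN   FN
#>   18   11 2369    0
```

The evolved formula leans repeatedly on `X4` (window standard deviation)
and amplitude terms (`X1`, `X8`) — spike windows carry a sharp
high-amplitude transient, so dispersion statistics separate them from the
1-50 Hz background (GP trees are often bloated; the depth cap, not
parsimony, is the only size control). Decisions are per 100 ms regional
window: all 18 truth-positive windows were detected, with 11 false
positives among 2380 truth-negative windows — mostly windows touching a
spike for less than the half-window labelling threshold.

Lower-level entry points: `compute_feature_table()` (windowed labelled
features), `evolve_formula()` (the GP search on a `fitness_context()`),
`knn_model()`/`knn_classify()`, `detect_spikes()`/`evaluate_detections()`.
A thin command-line front end with subcommands
`simulate | features | evolve | detect | evaluate | run-all` is installed
at `exec/spikegp`.

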