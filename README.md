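# conncca

Cross-modal prediction of whole-brain functional connectomes with sparse
canonical correlation analysis, evaluated on the manifold of symmetric
positive-definite (SPD) matrices.

## What problem this solves

Resting-state brain activity can be summarized as a *connectome* — a matrix
of dependencies between brain regions — from very different measurements:
slow hemodynamic signals, or the band-limited power envelopes of fast
electrophysiological recordings (delta 1–4, theta 4–8, alpha 8–13, beta
13–30, gamma 30–70 Hz). `conncca` is for researchers who want to quantify
how much these connectomes share, which modality predicts which, and which
individual connections carry the relationship.

The framework, per subject and modality:

1. **Band-limited power**: zero-phase second-order Butterworth band-pass,
   Hilbert envelope, and epoch handling — either the full-resolution
   envelope (WTS) or the envelope averaged within repetition-time epochs
   (AWE), with the first five epochs excluded.
2. **Connectome estimation**: Ledoit–Wolf shrinkage covariance
   Σ̂_λ = λI + (1−λ)Σ̂ with the analytic intensity λ, inverted and
   normalized to unit diagonal; the negated off-diagonals are partial
   correlations.
3. **Cross-modal model**: sparse CCA maximizing uᵀXᵀYv subject to
   ‖u‖₂ ≤ 1, ‖u‖₁ ≤ c₁ (and likewise for v), fit by the biconvex
   alternating algorithm with exact soft-threshold updates; penalties
   chosen by a permutation criterion; held-out connectomes predicted in
   both directions via ŷ = (x−x̄)ᵀU D V⁺ + ȳ.
4. **Evaluation**: geodesic (affine-invariant) distance
   d_AI(P,G) = √Σ log²λᵢ(G⁻¹P) under leave-one-out cross-validation, with
   a Wishart-based calibration that normalizes distances across matrix
   orders, plus Wilcoxon rank-sum / signed-rank comparisons.
5. **Connection selection**: randomized-Lasso stability selection over
   band-concatenated edges — repeated sCCA fits under random per-column
   weights from {0.5, 1} give each connection a selection probability.

A synthetic-data generator produces paired-modality cohorts with a planted,
tunable cross-modal coupling so every stage can be validated against ground
truth.

## Worked example

```r
library(conncca)

# a small coupled cohort: 8 subjects, 12 regions, one alpha-band envelope
spec <- synthetic_spec(n_subjects = 8, n_regions = 12, n_samples = 21600,
                       sampling_rate = 50, bands = list(alpha = c(8, 13)),
                       coupling = 0.8, subject_dev = 0.8,
                       deviation_rank = 2, deviation_dof = 8,
                       epoch_seconds = 0.72, seed = 42)
sim <- make_coupled_timeseries(spec)

# band-limited power connectome of subject 1
env  <- hilbert_envelope(bandpass(sim$subjects[[1]]$bands$alpha, c(8, 13)))
wts  <- wts_series(env, epoch_seconds = 0.72, drop_first = 5)
conn <- normalized_precision(shrinkage_covariance(wts))
conn
#> <connectome> normalized_precision, 12 regions, lambda = 0.0000

# edge datasets for both modalities (66 edges for 12 regions)
X <- edge_dataset_from_connectomes(lapply(sim$subjects, function(s)
  normalized_precision(shrinkage_covariance(
    wts_series(hilbert_envelope(bandpass(s$bands$alpha, c(8, 13))), 0.72, 5)))),
  band = "alpha", modality = "envelope")
Y <- edge_dataset_from_connectomes(lapply(sim$subjects, function(s)
  normalized_precision(shrinkage_covariance(s$slow))), modality = "slow")

# sparse CCA at permutation-selected penalties
sel <- select_penalties(X, Y, n_perm = 10, seed = 1)
fit <- scca_fit(X, Y, sel$c1, sel$c2, K = 2)
fit
#> <scca_fit> 2 component(s), p = 66, q = 66, n = 8
#>   penalties c1 = 4.874, c2 = 4.874
#>   canonical correlations: 0.983, 0.964

# leave-one-out cross-modal prediction, scored on the SPD manifold
report <- loo_predict(X, Y, grid = sel$diagnostics[, c("c1", "c2")],
                      n_perm = 10, seed = 2)
summary(report)
#> # A tibble: 2 × 5
#>   group        n median    iqr n_repaired
#>   <chr>    <int>  <dbl>  <dbl>      <int>
#> 1 x_from_y     8  0.600 0.0826          0
#> 2 y_from_x     8  0.907 0.231           0
```

The two rows are the per-direction medians of the geodesic distance between
each held-out subject's predicted and measured connectome: `y_from_x`
predicts the slow-modality connectome from the envelope connectome,
`x_from_y` the reverse; `n_repaired` counts predictions that had to be
projected back onto the SPD cone (none here). Smaller distances mean better
cross-modal prediction.

Other entry points: `calibrate_order_normalization()` / `normalized_dai()`
for comparing connectomes of different sizes, `concat_bands()` +
`randomized_scca()` + `top_selection()` for stability selection,
`coupled_prediction_experiment()` for a full prediction-vs-baseline
replicate on synthetic data, and `run_pipeline()` to execute the whole
chain from generated signals to reports in one call. See the vignette
(`vignettes/cross-modal-connectomes.Rmd`) for the model, its assumptions,
and all design choices.

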