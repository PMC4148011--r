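---
title: "Relating functional connectomes across modalities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating functional connectomes across modalities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conncca)
```

## The problem

Whole-brain functional connectivity can be measured with instruments that
see very different physics: a slow hemodynamic signal sampled every couple
of seconds, and fast electrophysiological recordings whose band-limited
power envelopes fluctuate on a similar slow timescale. Both can be
summarized, per subject, as a connectome: a symmetric positive-definite
(SPD) matrix of dependencies between brain regions. `conncca` implements a
statistical framework for asking how much the two kinds of connectome share:
it predicts one modality's connectome from the other across subjects with
sparse canonical correlation analysis (sCCA), scores the predictions by the
geodesic distance between SPD matrices, and identifies the individual
connections that carry the cross-modal relationship by stability selection.

Because no subject recordings ship with the package, a synthetic-data
generator produces cohorts with a known, tunable cross-modal coupling; every
claim the test suite makes is made against that ground truth.

## From signals to connectomes

**Band-limited power.** The fast modality is band-pass filtered into the
five canonical bands (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–70 Hz) with a second-order Butterworth filter applied forward and reverse
(`bandpass()`), so the net filter has zero phase and the squared magnitude
response of the one-pass design. Filter edge effects are bounded by
reflective padding of one epoch length plus the exclusion of initial epochs
below. The instantaneous amplitude is the magnitude of the analytic signal
(`hilbert_envelope()`). Two summarizations are supported: the full-resolution
envelope (WTS) and the per-epoch average (AWE), where epochs are consecutive
windows of `round(epoch_seconds * sampling_rate)` samples (2.16 s by
default, one repetition time of the slow modality) and the first five epochs
are dropped in both modes, mirroring the exclusion of initial volumes in the
slow modality (`awe_series()`, `wts_series()`). Whether the trailing partial
epoch's samples are retained in WTS is an explicit flag
(`include_partial`), since either convention is defensible; the default
trims to whole epochs for consistency with the epoch table.

**Covariance and partial correlation.** Per subject and band the region
series are summarized by a shrinkage covariance
\(\hat\Sigma_\lambda = \lambda I + (1-\lambda)\hat\Sigma\), with the
analytic Ledoit–Wolf intensity for the identity target
(`shrinkage_covariance()`): \(\lambda\) is the ratio of the summed sampling
variances of the covariance entries to the summed squared distance from the
target, clipped to [0, 1]. The sample covariance uses 1/(T−1) on centered
columns. This guarantees a well-conditioned SPD estimate even when regions
outnumber time samples. The connectome is the inverse covariance rescaled
to unit diagonal (`normalized_precision()`); its negated off-diagonals are
partial correlations, the dependence between two regions with all others
held fixed (`partial_correlation()`). Edges are the strict upper triangle in
row-major order (`vectorize_edges()`), one fixed convention package-wide.

## Comparing connectomes on the SPD manifold

The Frobenius norm ignores the geometry of SPD matrices, so predictions are
scored with the affine-invariant Riemannian distance
\[
d_{AI}(P, G) = \Big(\sum_i \log^2 \lambda_i\Big)^{1/2},
\qquad \lambda_i \in \mathrm{eig}(G^{-1}P),
\]
computed by Cholesky whitening and a symmetric eigendecomposition
(`dai()`); equality with the explicit matrix-logarithm form is asserted in
the tests to 1e-10. The metric is invariant to joint affine transformations
and to inversion, so covariance and precision comparisons agree.

Distances grow with matrix order, so comparisons across region sets (68
cortical vs 82 cortico-subcortical) use an order normalization: median
distances between random Wishart pairs are simulated over a range of orders
and a least-squares line is fit (`calibrate_order_normalization()`);
`normalized_dai()` divides by the fitted line at the matrices' order, which
is approximately division by the region count. The Wishart scale is
identity/dof with dof defaulting to twice the order — the minimal dof gives
near-singular draws and unstable medians — and both are exposed as
parameters since neither is canonical.

## Sparse CCA, penalty selection, prediction

Given the two edge matrices \(X\) (subjects × edges, fast modality) and
\(Y\) (slow modality), sCCA maximizes \(u^\top X^\top Y v\) subject to
\(\|u\|_2 \le 1, \|u\|_1 \le c_1\) (and symmetrically for \(v\)). With one
side fixed the update has a closed form: an L2-normalized soft-thresholding
of \(X^\top Y v\), with the threshold chosen so the L1 bound binds. The
threshold is found exactly — the L1/L2 ratio of the thresholded vector is
piecewise-smooth and non-increasing between order statistics of the input,
so the binding value solves a quadratic in a unique segment — with bisection
as a numerical fallback; a measure-zero corner (tied maxima with
multiplicity above \(c_1^2\), where no threshold can bind) falls back to
equal weights on `floor(c1^2)` tied coordinates. The alternation objective
is non-decreasing and is asserted per run. Components after the first
deflate the cross-product by \(\sigma_k u_k v_k^\top\) with
\(\sigma_k = u_k^\top Z v_k\). Initialization is the leading right singular
vector of the deflated cross-product by deterministic power iteration, so
fits are reproducible without a seed. When subjects are far fewer than
edges, the cross-product is applied through its thin factors rather than
materialized (identical results, much faster).

Penalties come from a permutation criterion (`select_penalties()`): each
grid point is scored by the gap between the Fisher-transformed canonical
correlation on the data and its distribution over row-permuted copies of
\(X\), standardized by the permutation spread; the default grid places
paired L1 bounds at fractions 0.1–0.8 of \(\sqrt{p}\). On extremely strong
planted fixtures this score saturates toward dense solutions (the observed
correlation saturates while the permutation spread keeps shrinking); this is
a property of the criterion, not of the implementation, and is why the
stability-selection stage documents that its fixed penalties should sit in
the sparse regime.

Prediction maps a held-out subject through the canonical space:
\(\hat y = (x - \bar x)^\top U D V^{+} + \bar y\) with \(D\) the diagonal of
per-component in-sample canonical correlations and \(V^{+}\) the
Moore–Penrose pseudoinverse (and symmetrically for the other direction).
In-sample correlations per component were chosen over re-estimated
post-deflation correlations because they are what the deflated objective
actually attains. Predicted edge vectors are devectorized to unit-diagonal
symmetric matrices; nothing guarantees positive definiteness, so predictions
are SPD-checked, repaired by eigenvalue flooring when needed
(`repair_spd()`, floor 1e-6 of the largest eigenvalue), and every repair is
counted and reported. Under the log-metric a floored direction is
expensive — repaired predictions legitimately score large distances — which
is the honest accounting: a prediction that left the SPD cone was a bad
prediction.

Leave-one-out evaluation (`loo_predict()`) re-selects penalties inside
every fold — costlier than selecting once globally, but the held-out subject
must not influence the penalties — fits with as many components as the
minimum rank of the training blocks, and scores both directions.

## Stability selection

To identify which connections drive the relationship, the per-band edge
datasets are concatenated column-wise (`concat_bands()`) so one pair of
sparsity parameters governs all bands, and the fit is repeated under random
per-column weights drawn from {0.5, 1} for both blocks
(`randomized_scca()`), the randomized-Lasso device: rescaling a column is
equivalent to perturbing its effective penalty. A column is selected when
its coefficient is nonzero in any retained component (configurable via
`K`); the selection probability is the count over repetitions. The default
repetition count is 1000 at desk scale; larger counts are a parameter.
`top_selection()` ranks within each band block and keeps the top fraction
(2% mirrors the published displays), ties broken by edge index.

## The synthetic cohort

The generator (`synthetic_spec()`, `make_coupled_timeseries()`) emulates
the statistical structure the analysis assumes:

- **Subject covariances.** A fixed well-conditioned correlation-like base
  \(B\) is transported per subject by the congruence
  \(C_s = A_s B A_s^\top\), \(A_s = I + \delta W_s\), where \(W_s\) is a
  Wishart draw whose rank-deficient scale spans a cohort-shared
  low-dimensional subspace (rank 3 by default, configurable). Three facts
  drove this design over a plain additive deviation. First, the congruence
  guarantees SPD for any \(\delta \ge 0\). Second, the affine-invariant
  metric measures *relative* differences, so additive deviations do not
  scale between-subject distance monotonically — empirically the median
  inter-subject distance was flat or decreasing in the deviation scale —
  whereas the multiplicative form is monotone by construction. Third,
  individual differences must occupy a shared subspace: if every subject
  deviates in fresh random directions, a model trained on other subjects
  cannot predict anything about a new subject even in principle, and
  cross-modal prediction degenerates to the group mean. Real cohorts have
  structured individual differences; the shared-subspace Wishart makes that
  explicit and tunable.
- **Slow modality.** A temporally smoothed Gaussian series with
  cross-sectional covariance exactly \(C_s\), sampled at the epoch
  (repetition-time) resolution.
- **Band envelopes.** Per band, an independent smoothed Gaussian series
  with covariance \(c\, C_s + (1-c)\, Q_{s,b}\) — \(c\) is the coupling,
  \(Q_{s,b}\) an independently structured SPD matrix — exponentiated (a
  log-normal envelope is positive by construction) and used to
  amplitude-modulate a narrowband carrier: band-filtered white noise
  normalized by its own analytic-signal magnitude, so the carrier
  contributes realistic bandwidth but no amplitude structure of its own.
  Envelopes and carriers are independent across bands, so inter-band
  envelope correlations are low, as observed in real band-limited-power
  data.

What the generator does *not* emulate: volume conduction and source
leakage, acquisition artifacts, head geometry, nonstationarity, and
1/f-type spectra. Passing tests therefore demonstrate that the statistical
machinery recovers planted structure under the model's assumptions — not
that those assumptions hold for any particular recording system.

## Study-scale conditions used by the test suite

The property checks run at a deliberate desk scale: 17 subjects, 30
regions (435 edges), one alpha-band envelope, 64 800 fast samples at 50 Hz,
and a 0.72 s epoch for the slow modality — a fast multiband-style
repetition time, giving 1800 slow samples so inter-subject structure rises
above covariance-estimation noise. The coupled condition uses coupling 0.8
and subject deviation 0.8 on a rank-2 shared subspace with 8 degrees of
freedom; the decoupled control sets coupling to 0 and changes nothing else.
Under these conditions leave-one-out sCCA prediction of the slow connectome
from the envelope connectome beats the strongest subject-independent
reference — the distance to the element-wise group mean of the training
subjects' connectomes — when coupling is present, and fails to beat it when
coupling is absent (the overfit canonical map injects deviation along
directions unrelated to the held-out subject). The mean pairwise distance
to other subjects is also reported; it is a weaker reference, beaten by
any mean-like predictor, so the group-mean comparison is the informative
one. The Wishart calibration runs orders 10–100 with 100 pairs per order;
the shrinkage study uses 30 regions and 50 samples over 100 replicates;
linkage recovery uses 17 subjects with 200+200 edges and a planted support
of 5 at high signal-to-noise.

## Numerical choices and degenerate inputs

- Symmetry is enforced to 1e-10 and re-symmetrized after inversions and
  eigen-reconstructions; SPD checks use a strict eigenvalue tolerance.
- A constant region (zero variance) pulls the shrinkage estimate to the
  identity rather than erroring, recording \(\lambda = 1\).
- `scca_fit` caps the component count at the minimum rank of the centered
  blocks, with a warning; an exhausted cross-product truncates the
  component list, also with a warning.
- The permutation score of a grid point with zero permutation spread is
  \(-\infty\) (never selected).
- Zero paired differences are dropped in the signed-rank test; an all-zero
  difference vector is reported as degenerate with p = 1 and a warning.
- Rank tests enumerate exactly (rank-sum over all assignments, signed-rank
  over all sign patterns) up to combined size 12 and use tie-corrected
  normal approximations beyond; base R's `wilcox.test` is the independent
  reference in the tests, not the implementation.

## Known limitations

- The pseudoinverse back-projection can amplify noise when canonical
  vectors across components are nearly collinear; repairs are counted,
  and the distance penalty for leaving the SPD cone is intentionally not
  softened.
- The permutation penalty criterion saturates toward dense solutions on
  very strong signals; interpret selected penalties accordingly and use
  explicitly sparse penalties for stability selection.
- Order normalization is calibrated for Wishart-distributed pairs; it
  transfers to connectome-like matrices only as an approximation (division
  by a line in the order), exactly as intended by its definition.
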