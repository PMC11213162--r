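---
title: "Graph frequency bands and connectivity features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph frequency bands and connectivity features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfcband)
```

## The problem

Progressive mild cognitive impairment (pMCI) — MCI that converts to
Alzheimer's disease within follow-up — is clinically indistinguishable from
stable MCI (sMCI) at baseline, yet the two differ in resting-state functional
connectivity (FC). `gfcband` implements a graph-signal-processing pipeline
for this discrimination problem: ROI time series are decomposed into *graph*
frequency bands defined by a subject-specific connectivity graph, whole-network
features are computed per band, and a wrapper-selected SVM classifies the
groups under nested cross-validation. Because the clinical recordings that
motivate the pipeline are access-controlled, the package ships a synthetic
cohort generator that reproduces the acquisition geometry and lets every
stage be exercised, calibrated and power-tested without any download.

## The generative model of the synthetic cohort

Each subject is filtered Gaussian noise: a white multivariate Gaussian draw
with a target correlation matrix imposed by its Cholesky factor, then
band-pass filtered per ROI and truncated. Defaults mirror a typical
ADNI-style protocol: `n_volumes = 140` at `tr_seconds = 2` with the first
`n_discard = 5` volumes dropped (so `T = 135`), signals confined to
0.01–0.1 Hz, and group sizes 142/136. Group B's correlation matrix is the
base matrix with the `effect_edges` shifted by `effect_size` and re-projected
to the nearest positive semi-definite correlation matrix (eigenvalue clipping
at `1e-8`, re-normalization to unit diagonal); the generator refuses if the
repair moves any planted correlation by more than 0.02 or pushes it outside
(−1, 1).

Three deliberate design choices:

* **Zero-lag fidelity.** Every ROI passes through the *same* linear filter,
  so the zero-lag correlation of the white input is preserved in expectation;
  the planted correlations remain the generating truth of the filtered
  series. Tests verify recovery to ±0.05 at T = 20,000.
* **Common random numbers across groups.** Subject *i* of either group uses
  seed `seed + i`, so with `effect_size = 0` the groups are identical
  realizations and any downstream group difference is exactly attributable
  to the planted covariance. This is a paired-noise variance-reduction
  device; the null-calibration tests that require independent groups draw
  their samples directly rather than through the generator.
* **Filter order.** The band-pass is a zero-phase (forward–backward)
  order-4 Butterworth. Its stop-band attenuation puts well over 95% of each
  series' power inside the configured band for records long enough to
  resolve the band edges; a 135-sample periodogram necessarily leaks a few
  percent through spectral smearing regardless of the filter, which is why
  the spectral-content test measures at T ≈ 2000.

What the generator does *not* emulate: head motion, physiological nuisance,
scanner drift, spatial structure (there is no volumetric stage — the model
starts at ROI time series), non-stationarity, and non-Gaussian amplitude
distributions. A passing test suite therefore certifies the *pipeline
mechanics and statistical calibration*, not performance on real scans.

## Sliding-window FC and the sparse adjacency

FC is the taper-weighted Pearson correlation computed in windows advanced by
one TR, aggregated per edge by the median across windows. The taper is a
50-TR rectangle convolved with a 3-TR-σ Gaussian (truncated at ±4σ), giving
a 74-TR window and hence `floor((135 − 74)/1) + 1 = 62` windows at study
geometry. Two interpretation choices were open:

* The taper enters as *observation weights* in the correlation, not as a
  multiplier of the signal — the standard tapered-window dynamic-FC
  practice.
* Only fully contained windows are used (no padding), and the median uses
  the midpoint rule for even counts.

The GSP adjacency is group-informed: for every edge, the full-band FC values
are compared between groups with a two-sided Wilcoxon rank-sum test (normal
approximation with tie and continuity correction; an edge constant across
all subjects gets p = 1). Edges with p < α form a mask shared by all
subjects; each subject keeps its *own* FC values on masked edges. No
significance threshold or multiplicity correction is prescribed by the
method's sources, so the package defaults to α = 0.05 uncorrected and
exposes both `alpha` and an `fdr` (Benjamini–Hochberg) switch. Monte-Carlo
tests confirm the screen retains ≈ α of null edges (±0.02 over 500
replicates).

## Graph spectra and band filtering

The combinatorial Laplacian is `L = D − A`. The sparse FC carries signed
correlations; eigenvalue ordering is only a frequency ordering when `L` is
positive semi-definite, so by default the adjacency magnitudes are used
(`signed_laplacian = TRUE` keeps raw weights for sensitivity analyses).
Eigenvectors are ordered by ascending eigenvalue with a deterministic sign
convention (largest-magnitude entry positive, first index on ties), making
spectra run-to-run reproducible even under degenerate eigenvalues.

Band filtering is `x_F = V G Vᵀ x` with `G` a 0/1 diagonal selector. The
low band takes the first `floor(M/3)` modes, the high band the last
`floor(M/3)`, the middle band the remainder — reproducing the 45/46/45
split at M = 136 and generalizing to any M ≥ 3. The three projectors are
orthogonal, idempotent and sum to the identity (tested to 1e-10 at
M = 136). Each subject's spectrum comes from its own sparse adjacency; a
disconnected adjacency is allowed (extra zero modes fall in the low band)
and logged with its component count.

## The 100-feature set

Twenty-five metrics per band × four bands (FFB plus the three filtered
bands): 9 global graph metrics, 7 MST metrics, 5 triadic metrics, 2 hub
tendency metrics and 2 link counts. Numerical conventions that the metric
names alone do not fix:

* **Paths** use the positive-weight subgraph with edge length `1/w` (the
  Brain Connectivity Toolbox convention); negative edges carry no path
  information.
* **Clustering** is the Onnela geometric-mean weighted triangle formula on
  positive weights; **eigenvector centrality** uses `|FC|` so
  Perron–Frobenius guarantees a real non-negative principal vector;
  **modularity** is Louvain at resolution 1 on positive weights, best of 10
  restarts under a fixed seed (`louvain_seed`, default 42) so feature tables
  are deterministic.
* **MST** is built on `d = 1 − w` (the single-linkage dendrogram backbone;
  tests verify the Kruskal equivalence) and its metrics use the unweighted
  tree topology (hop eccentricities, normalized betweenness), with a
  `weighted_tree` flag for the weighted variant.
* **Triads** are ROI triples with all three edges nonzero, classified by
  their count of positive edges; the network energy is the negative mean
  triple product over qualifying triads. On median-aggregated FC matrices
  essentially every triple qualifies.
* **Negative hub tendency** uses the magnitudes of negative weights, so both
  TMH values are non-negative.
* Metrics undefined on a given matrix (e.g. path metrics of an all-negative
  matrix, TMH of a matrix with no negative links) are flagged and imputed
  with the cohort median at table assembly, with a logged count; a feature
  undefined for the entire cohort is set to 0.

Every family is validated against an independent brute-force oracle
(Floyd–Warshall, Kruskal, exhaustive triple loops, two-pass strength loops)
at M ≤ 12, and all features are ROI-permutation invariant.

## Wrapper feature selection

Fitness of a candidate mask is the mean accuracy of an RBF-SVM over
stratified 5-fold cross-validation *on the outer training data only*, with
per-fold standardization; an empty mask scores 0. Fitness values are
memoized per mask within a run.

**Binary PSO.** The search space is a bit mask, so the canonical continuous
update (inertia 0.72, cognitive and social coefficients 1.5, swarm 20) acts
on velocities that are clipped to ±4 and mapped through a sigmoid to
per-bit Bernoulli resampling. The global-best topology is used. The
iteration budget (default 50) is a cost choice, exposed in
`pso_config()`.

**Simulated annealing.** One uniformly chosen bit is flipped per step;
improvements over the current mask are always accepted and worse neighbors
with Boltzmann probability `exp(−θ/T)`, where θ is measured against the
*best-so-far* fitness. Cooling is geometric from T₀ = 10 (ratio 0.95 every
20 steps by default, floor 1e-3); schedule parameters are cost choices
exposed in `sa_config()`.

Both optimizers return the best-ever mask, whose recorded fitness always
equals an independent recomputation, and a non-decreasing best-so-far trace.
No cardinality penalty enters the fitness — parsimony is reported as an
outcome, not optimized.

## Nested evaluation

The outer loop is stratified 10-fold cross-validation with seeded shuffling;
within each fold, standardization statistics, the selector and the SVM see
only the training data, and the held-out fold is predicted once. Sensitivity
is the detection rate of the progressive group (positive class = second
factor level, "B"). Headline accuracy/sensitivity/specificity come from the
pooled confusion counts; mean-of-fold metrics are reported alongside since
the convention is ambiguous in the field. ROC curves pool the decision
values of all outer test folds; AUC is trapezoidal and cross-checked against
pROC. SVM hyperparameters default to C = 1 with the variance-scaled
`gamma = 1/(d · var(X))` rule and no tuning, reflecting that no search is
part of the method.

## Problem sizes used by the shipped tests and acceptance script

All empirical checks run on synthetic data at sizes chosen to exercise the
statistics well in a few minutes on a single core; they are the package's
standing study conditions, stated here once:

* bookkeeping cohort: M = 20 ROIs, 10 + 10 subjects;
* planted-connectivity cohort: M = 20, 60 + 60 subjects, Δr = 0.4 on ten
  disjoint edges (the pipeline default), classified without selection;
* null calibration: 210 edges, 20 + 20 subjects, 500 replicates (200 in the
  acceptance script);
* selector recovery: 5 informative of 100 features at d = 1.5, 100 + 100
  subjects, PSO at 10 iterations and SA at T₀ = 10 with ratio 0.8, 10
  flips per level, floor 0.05, unioned over seeded repeats.

## Known limitations

* Per-subject spectra make band features depend on the group-informed edge
  mask, which is computed on the full cohort before cross-validation — this
  mirrors the method as described, but means the *band definition* (not the
  classifier) has seen all labels; treat reported accuracies accordingly.
* The band split rule fixes |LFB| = |HFB| = floor(M/3); no data-driven band
  boundaries.
* Only the combinatorial Laplacian is offered (no normalized variant), only
  SVM-RBF is offered as a classifier, and only PSO/SA as selectors.
* The synthetic generator is stationary and Gaussian; none of the artifact
  structure of real rs-fMRI is modeled.
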