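---
title: "High-order connectivity networks and broad learning: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-order connectivity networks and broad learning: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hofcn)
```

## The problem

Resting-state fMRI yields, per subject, a matrix of BOLD time courses: `T`
time points by `M` regions of interest (ROIs). The classical *low-order*
functional connectivity network (Lo-FCN) is the `M x M` matrix of pairwise
Pearson correlations

$$\rho_{uv} \;=\; \frac{\sum_t (u_t-\bar u)(v_t-\bar v)}
  {\sqrt{\sum_t (u_t-\bar u)^2}\,\sqrt{\sum_t (v_t-\bar v)^2}},$$

which sees only *pairs* of regions. Many conditions, however, are thought to
perturb coordinated activity across *groups* of regions. This package builds
a *high-order* connectivity representation from a hypergraph over the ROIs,
compresses it with a stacked autoencoder, and classifies subjects with a
Broad Learning System (BLS), evaluated under stratified repeated k-fold
cross-validation.

## Hypergraph high-order connectivity

Each ROI becomes a vertex. Taking each vertex in turn as a *centre*, one
hyperedge is formed from the centre plus its `k` nearest vertices in
Euclidean distance, so there are exactly `M` hyperedges of `k + 1` vertices
each. The structure is encoded by the binary incidence matrix
`H (M x M_e)`, hyperedge weights `W` (all 1 by default), vertex degrees
`d(v_i) = sum_j w_j H_ij` and hyperedge degrees `delta(e_j) = sum_i H_ij`.
From these,

$$\Delta = D_v - H\,W\,D_e^{-1}H^{\mathsf T}, \qquad
  \Delta_{\text{norm}} = I - \underbrace{D_v^{-1/2} H\,W\,D_e^{-1}
  H^{\mathsf T} D_v^{-1/2}}_{S}.$$

`Delta` annihilates the constant vector and both Laplacians are positive
semidefinite with the normalized spectrum in `[0, 2]` — properties the test
suite verifies on hundreds of random instances against brute-force
accumulation and dense eigensolvers.

Design choices that the construction leaves open, and how this package
resolves them:

* **What "distance between regions" means.** The default feature of ROI `i`
  is row `i` of the subject's Lo-FCN — its connectivity profile — because it
  is scale-consistent across subjects and makes the high-order network an
  explicit refinement of the low-order one. Distances on the raw time
  courses are available via `feature_space = "timeseries"`.
* **Centre membership.** The centre belongs to its own hyperedge, so every
  hyperedge has exactly `k + 1` vertices and no vertex is ever isolated.
* **Ties.** Equal distances are broken toward the lowest vertex index;
  results are therefore identical across platforms and BLAS libraries.
* **Duplicate hyperedges** are kept as distinct columns, fixing `M_e = M`
  and the shape of `H`.
* **Which matrix is "the" high-order network.** The normalized association
  `S` is vectorized (strict upper triangle, row-major) as the subject's
  feature vector: it is symmetric, bounded, and exactly the operator the
  normalized Laplacian is built from. `laplacian_norm` and `H` itself are
  exportable alternatives.
* **`k = 5`** by default, the operating point at which this architecture is
  usually run; it is a plain config knob (`pipeline_config(k = ...)`).

## Autoencoder

The `M(M-1)/2`-dimensional feature vectors are compressed by a stacked
autoencoder: `L = 3` tanh encoder layers with geometrically interpolated,
strictly decreasing widths, and a mirrored *linear* decoder (the decoder
map is affine with no nonlinearity at every layer). Training minimizes mean
squared reconstruction error by mini-batch backpropagation.

Numerical choices:

* **Optimizer: Adam** (`optimizer = "adam"`, rate `1e-3`, batch 32). Plain
  SGD at small rates leaves a deep tanh stack essentially at its
  initialization for any reasonable epoch budget on data of this shape;
  Adam converges reliably in ~100 epochs. Plain SGD remains available.
* **Initialization**: Glorot-uniform, seeded; training is bitwise
  reproducible from the seed.
* **Standardization**: inputs are z-scored per feature using *training-fold*
  statistics only, both before the autoencoder and again after encoding
  (tanh saturates otherwise; fold-wise fitting prevents leakage).
* **Whole-stack joint training**, not greedy layer-wise pretraining: the
  model is one encoder/decoder pair of L layers.
* The autoencoder is refitted inside every training fold. Fitting it once
  on all data would leak test information into the representation; if
  published results were produced that way, accuracies are not directly
  comparable.
* `loss_history` carries the initialization loss as its first element, then
  one entry per epoch, so the "training never worsens reconstruction"
  invariant is checkable from the returned object.
* **Bottleneck width**: geometric interpolation ends at 512 for atlas-scale
  inputs (`D ~ 2e4`); the pipeline default is 64, sized for the desk-scale
  synthetic cohorts below.

## Broad Learning System

BLS is a flat random-feature network. With input `X (N x D)`:

$$Z_i = \phi(X W_{e_i} + \beta_{e_i}),\quad i = 1..n \qquad
  H_j = \delta(Z W_{h_j} + \beta_{h_j}),\quad j = 1..m$$

with `Z = [Z_1 ... Z_n]`, and the model output is `Y = [Z | H] W`. All the
`W_e, beta_e, W_h, beta_h` are drawn once, uniform on `[-1, 1]`, from a
stored seed and never trained. Only the output weights are learned, in
closed form, by ridge regression against one-hot class targets:

$$W = \arg\min_W \|AW - Y\|_2^2 + \lambda\|W\|_2^2,
  \qquad A = [Z\,|\,H].$$

Implementation notes:

* The solve uses the exact ridge identity
  `(A'A + λI)^{-1}A'Y = A'(AA' + λI)^{-1}Y`, choosing the route with the
  smaller Gram matrix. With many more nodes than subjects this keeps the
  system small and well-conditioned even at the default `λ = 1e-8`, which
  is small enough to approach interpolation yet keeps the solve stable.
* Node-count accounting: `n` mapping groups of `w` nodes (the "window
  size") and `m` enhancement groups of `h` nodes; the defaults
  `n = 20, w = 100, m = 1, h = 10` correspond to the usual multi-cohort
  operating point of this architecture. All four counts are independent
  config keys, so other accountings of "total nodes" are expressible.
* Both nonlinearities default to tanh (tansig is the same function); an
  identity option exists for tests that need a linear regime.
* Incremental width/data updates and sparse-autoencoder fine-tuning of the
  mapping weights — features of the broader BLS literature — are out of
  scope: only batch training is implemented.
* Tied argmax scores decode toward the earlier class in `class_codes`.

## Cross-validation and metrics

`run_pipeline()` pools all subjects (a site column is carried but not used
for splitting by default), stratifies folds by class so that per-class
counts differ by at most one across folds — a deliberate strengthening of
plain random splitting that avoids degenerate single-class folds — and
repeats the fold assignment `n_repeats` times with derived seeds. Each
repeat/fold cell fits scalers, autoencoder and BLS on the training
subjects only. Reported are accuracy, sensitivity (positive = patient
class), specificity and precision as mean ± sd over all cells; a metric
with an empty denominator is `NA`, never 0. Every stage's seed is derived
deterministically from the single `cv` seed, so a run is reproducible from
one integer.

## Synthetic cohorts

`generate_dataset()` emulates a two-class resting-state cohort at desk
scale: ROIs are partitioned into modules; each subject's series is drawn
from a zero-mean multivariate normal whose correlation is
`within_module_corr` inside modules and a class-specific value between
modules, plus independent Gaussian observation noise. The classes differ
*only* in between-module coupling — exactly the multi-region structure the
hypergraph representation targets, and a signal to which no single marker
responds.

Defaults: 60 subjects per class, `M = 40` ROIs in 4 modules, `T = 150`
time points, within-module correlation 0.6, between-module 0.1 (control)
vs 0.5 (case), noise sd 0.2. These sizes exercise every stage in minutes
on one CPU. Observation noise attenuates all observed correlations by the
factor `1/(1 + noise_sd^2)` (~4%), which the long-series generator test
accounts for within its tolerance.

What the generator does *not* emulate: hemodynamic autocorrelation, site
and scanner effects, motion artifacts, or heterogeneous subject-level
connectivity. Passing tests therefore demonstrate that the pipeline
recovers planted multi-region correlation structure and is honest on null
data — not that any particular accuracy will transfer to real cohorts.

## Verification summary

The test suite checks, among others: Pearson matrices against a
brute-force scalar-formula loop (1e-12); hyperedge sets against an
exhaustive nearest-neighbour scan; Laplacian algebra against triple-loop
accumulation and closed forms (`I - J/n`; the two-pair block form);
positive semidefiniteness and the `[0, 2]` normalized spectrum on 200
random hypergraphs; autoencoder gradients against central finite
differences (1e-5); BLS weights against an independent dense solve (1e-8)
and a BFGS minimizer (1e-5); and end-to-end behaviour on the synthetic
cohorts — planted-signal recovery with 10-fold CV accuracy at or above
0.9, and chance-level accuracy (within the 95% binomial interval around
0.5) on matched-null and label-permuted data. `scripts/acceptance.R`
recomputes the cohort-level metrics from scratch at the default sizes
(120 subjects, 10-fold CV, one repeat).

## Known limitations

* All tensors are dense base-R matrices; atlas-scale inputs
  (`M = 200`, `D = 19900`) train the autoencoder in minutes-to-hours on a
  single CPU rather than seconds.
* The hypergraph weights are fixed at 1; learned hyperedge weights and
  group-level hypergraphs are out of scope.
* Single-level cross-validation with a fixed configuration: no nested
  hyperparameter search is performed (an inner tuning loop would be the
  natural extension where enough data exist).
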