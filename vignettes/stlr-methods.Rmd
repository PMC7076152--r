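---
title: "Group-similarity constrained network estimation: models, solver and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-similarity constrained network estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stlrnet)
```

## The estimation problem

Resting-state activity recorded from `N` brain regions over `T` time points
yields, per subject, a matrix `X` (`T x N`). A functional brain network
summarizes the pairwise dependence structure of the columns of `X`. Two
families of estimators are in common use:

* **full correlation** — the Pearson correlation matrix, optionally
  sparsified by keeping the strongest edges (`pearson_network()`,
  `threshold_network()`);
* **regression / partial correlation** — each region's signal is regressed
  on all the others, `min_W ||X - X W||_F^2` with `diag(W) = 0`, so that
  `W[, j]` captures the conditional association of region `j` with the rest
  after the confounding influence of third regions is regressed out. The l1
  penalty of `estimate_sr()` makes this well posed and sparse.

Every regularized estimator in this package is an instance of
`min_W f(X, W) + penalties`, differing only in the penalty:

| method | function | penalty |
|---|---|---|
| SR  | `estimate_sr()`  | `lambda ||W||_1` per subject |
| SLR | `estimate_slr()` | `lambda ||W||_1 + gamma ||W||_*` (matrix trace norm) per subject |
| GSR | `estimate_gsr()` | `lambda_group ||W||_{2,1}` across subjects |
| TLR | `estimate_tlr()` | `gamma ||W||_*` (tensor trace norm) across subjects |
| STLR| `estimate_stlr()`| `lambda ||W||_1 + gamma ||W||_*` (tensor) across subjects |

Columns are standardized (zero mean, unit Euclidean norm) before any
regression-based estimation: centering is already implicit in correlation,
and unit norm makes one penalty grid comparable across data sets.

## The group-similarity prior

Cohort subjects share most of their network architecture. GSR encodes this
through joint edge selection: each connection, taken as a vector across all
`K` subjects, is shrunk as a group, so an edge survives for everyone or for
no one. That is a hard constraint on the *support* and it is known to
over- or under-penalize: an edge genuinely present in half the cohort is
forced in or out for all.

The tensor low-rank prior is softer. Stack the subject networks into a
three-way tensor `W` (`N x N x K`) and penalize its rank: if the cohort
shares a backbone, the slices are nearly parallel and the tensor is nearly
low-rank, yet each subject can still deviate in its own direction. Since
rank is intractable, the penalty is relaxed to a trace norm computed from
the CP/PARAFAC decomposition

`W = sum_r lambda_r a_r o b_r o c_r`, `||W||_* = sum_r lambda_r`,

with unit-norm factors and nonnegative weights. Its proximal shrinkage
(`prox_trace_tensor()`) decomposes the iterate, soft-thresholds the weights
by the scaled penalty, and reconstructs. Two things are worth stating
plainly:

* this CP-weight sum is **not** the convex tensor nuclear norm; we implement
  the shrinkage literally as defined, with no convex reformulation, so the
  overall iteration is a well-defined algorithm rather than the exact
  minimizer of a convex objective;
* with a single slice (`K = 1`) the CP of a matrix is non-identifiable
  (infinitely many exact factorizations with different weight spectra), while
  its canonical decomposition is the SVD; `prox_trace_tensor()` therefore
  applies exact singular-value soft-thresholding in that degenerate case,
  which is the unique continuous limit of the intended operation.

### Naming of the two penalty weights

Both penalties are exposed as named parameters — `lambda_sparse` for the l1
term and `gamma_lowrank` for the trace term — rather than positional Greek
symbols, because the common symbolic convention is ambiguous across
descriptions of this model family. Every function in the package uses the
names, never the position.

## The solver

`prox_solve()` (driving all regularized estimators) iterates, in this fixed
order per iteration:

1. **gradient step** on the data-fit `1/2 sum_k ||X_k - X_k W_k||_F^2`,
   whose gradient is `X'X W - X'X` per slice;
2. **tensor (or matrix) trace-norm shrinkage** with threshold
   `a_t * gamma_lowrank`;
3. **l1 soft-thresholding** with threshold `a_t * lambda_sparse` (or group
   l2,1 shrinkage for GSR);
4. **diagonal re-zeroing** of every slice.

Stopping: relative Frobenius change of the tensor below `tol` (default
`1e-5`) or `max_iter` (default 100) iterations; non-convergence returns the
current iterate with a warning and `converged = FALSE` in the diagnostics.

Numerical design choices, each of which was forced by observed behavior on
test problems:

* **Zero-diagonal constraint as a subspace projection.** The gradient's
  diagonal is projected out before the step, so every candidate iterate is
  feasible. Zeroing the diagonal only *after* an unconstrained step breaks
  the monotonicity that the line search certifies — the post-hoc projection
  can raise the objective by more than the step lowered it, and on
  ill-conditioned subjects the combined map visibly diverged while every
  individual step "decreased" the objective. The prox outputs are still
  re-zeroed (step 4), since the trace shrinkage can reintroduce diagonal
  mass.
* **Line search.** The step `a_t` starts at 0.001 and backtracks by halving
  (at most 30 times) until the quadratic upper-bound condition
  `f(W - aG) <= f(W) - (a/2)||G||^2` holds; acceptance without any halving
  doubles the step for the next iteration, capped at 1.0. The quadratic
  bound — rather than plain decrease — keeps the accepted step inside the
  `1/L` stability region; plain decrease admits steps up to twice that and
  oscillates. In addition the cap shrinks permanently to the last step that
  needed backtracking: without this, the step alternates between `a` and
  `2a`, the prox thresholds alternate with it, and the iterate cycles
  between two fixed points instead of converging.
* **Deterministic, cold CP per iteration.** The shrinkage uses a single
  SVD-based (HOSVD-style) initialization with a fixed seed, so the prox is a
  deterministic function of its input and the loop can settle at a fixed
  point. Warm-starting the ALS from the previous iteration's factors looks
  attractive but accumulates CP *degeneracy*: across hundreds of chained
  refits the factor weights inflate in nearly-cancelling pairs while the
  reconstruction stays put, which corrupts both the shrinkage and the
  reported penalty value. `cp_decompose()` called directly keeps its
  default of three initializations (SVD plus two seeded random restarts,
  best residual wins).
* **Objective monitoring.** The diagnostics carry
  `f + lambda_sparse * ||W||_1 + gamma_lowrank * sum(shrunk CP weights)` per
  iteration. Because the composition of the two shrinkages is only an
  approximation to the proximal operator of the summed penalty, this
  monitored value is guaranteed to decrease only through its data-fit part;
  in the mild-penalty regime where the estimators actually operate (grid
  points around `2^-4 ... 2^-2` at the problem sizes below) it ends below
  the value at the zero initialization, and the test suite asserts exactly
  that. At strong shrinkage the monitored value can end above `F(0)`; the
  returned tensor is still the algorithm's fixed point.
* **CP rank.** `cp_rank = "auto"` uses `min(N, K)` capped at 30. At that
  rank the CP of a noisy stacked tensor is an imperfect fit (relative
  residuals of 0.3 are normal mid-iteration); what matters for the prior is
  the dominant shared components, which the shrinkage keeps.

## Synthetic cohorts

`make_cohort()` is a first-class module, not a test fixture. It generates:

1. a **backbone** — `ceiling(density * N(N-1)/2)` edges shared by both
   classes, weights drawn with magnitude `U(0.25, 0.45)` and random sign;
2. **differential edges** — `n_diff_edges` extra edges present only in
   class 1, with magnitude `effect_size`;
3. **subjects** — each subject's true network adds `N(0, jitter)` to every
   backbone edge;
4. **signals** — `T` i.i.d. draws from the zero-mean Gaussian with precision
   `Omega = c I - W_true`, `c = |min eigenvalue| + 0.5`. Off-diagonal
   precision entries are then proportional to the true edge weights, so the
   regression estimators recover exactly the planted support, and the
   two-node case has the closed-form partial correlation `w / c` used in the
   tests. If any subject's `Omega` would fall below a 0.05 eigenvalue
   margin, all subjects are rescaled by one common factor (class contrasts
   are preserved; per-subject rescaling would distort them).

Defaults — `N = 20`, `T = 150`, `K = 20` per class, backbone density 0.1,
jitter 0.1, 8 differential edges of weight 0.35 — are a desk-scale version
of a typical single-site resting-state study (about a hundred regions, a
hundred-plus volumes, a hundred-odd subjects), chosen so a full nested-CV
experiment runs in minutes on one CPU. What the generator deliberately does
**not** model: temporal autocorrelation (samples are i.i.d.; real BOLD is
smooth), hemodynamics, head motion, and site effects. Passing tests
therefore demonstrate correctness of the estimation and validation
machinery under the generative model the estimators assume — not robustness
to fMRI artifacts.

## Classification pipeline

`loocv_classify()` implements the standard connectome-classification
protocol with strict leakage control:

* features are the `N(N-1)/2` upper-triangle edge weights of the finalized
  (symmetrized) networks, in fixed row-major order;
* each outer leave-one-out fold re-runs feature selection — pooled-variance
  two-sample t-test, keep `p < 0.01`, no multiplicity correction — and
  z-scoring with training statistics only, then fits a linear SVM with
  `C = 1`;
* hyper-parameters are chosen by an inner leave-one-out loop on the training
  set over the supplied grids, with ties broken toward weaker
  regularization;
* for the **group estimators** the joint estimation is re-run inside every
  outer fold on the training subjects; after the grid choice, the held-out
  subject's network is obtained by appending its *signals* to the training
  cohort and taking its slice of the joint solve. Its label never enters
  selection, scaling or the classifier. For per-subject estimators the
  networks depend only on each subject's own data, so they are computed once
  per grid point without any leakage.
* if no feature passes the filter in some fold, the fold trains on all
  non-degenerate features instead. The two obvious alternatives misbehave
  on null data: a training-majority vote always opposes the held-out label
  in balanced leave-one-out folds, and picking the single best sub-threshold
  feature maximizes selection overfit. Even with this choice, leave-one-out
  accuracy on null cohorts is a high-variance quantity (fold predictions are
  strongly correlated); the chance-band checks in the test suite average
  over several generator seeds for that reason.

`consensus_connections()` intersects the per-fold selection masks and ranks
the surviving edges by mean p-value; `region_degree_ranking()` counts
incident consensus edges per node.

## Graph-theory characterization

Metrics are computed on binary graphs (`binarize()`): by default an edge
exists where the estimated weight is nonzero beyond `1e-6` — the
estimator's own sparsity decision — with a fixed-density alternative for
dense (correlation) networks. Negative weights count by magnitude.
Conventions where the literature leaves room:

* path length `Lp` averages over *connected* pairs only; global efficiency
  counts disconnected pairs as 0 — both stated explicitly since sparse
  networks are routinely disconnected;
* normalization uses degree-preserving double-edge-swap nulls
  (`10 |E|` attempted swaps, `n_null = 100` by default, seeded);
  `gamma = Cp/Cp_rand`, `lambda = Lp/Lp_rand`, `sigma = gamma/lambda` by
  construction;
* modularity uses agglomerative greedy (CNM) optimization; the merge
  dendrogram is cut at the modularity-maximizing step and `Q` is recomputed
  from that membership (the two can disagree on tie-heavy graphs);
* hubs are nodes with degree above mean + 1 SD (configurable), the simplest
  of the standard hub criteria.

All metrics are validated against brute-force oracles (triangle counting,
Floyd–Warshall, exhaustive bipartition search for two-clique modularity) on
small graphs in the test suite.

## Problem sizes used by the tests and the acceptance script

The recovery benchmark uses `N = 20`, `T = 300`, 10–20 subjects per class,
jitter 0.1, with grid search for both methods (`2^-5 ... 2^1` for SR,
`2^-4 ... 2^-2` in both axes for STLR); the classification ordering runs
five seeded cohorts at `N = 10`, `K = 5` per class, `T = 100` with six
differential edges of weight 0.6; null-cohort calibration uses 20 subjects
and no differential edges. These sizes were chosen as the smallest at which
the studied effects are comfortably away from sampling noise.

## Known limitations

* The tensor shrinkage is a heuristic proximal step for a non-convex
  penalty; no global-optimality statement attaches to the returned tensor.
* Convergence slows near penalty values where a CP component sits exactly at
  the shrinkage threshold; the solver then reports `converged = FALSE` at a
  stable, usable iterate.
* The generator's i.i.d. sampling means estimated effective sample sizes are
  optimistic relative to autocorrelated BOLD; absolute accuracies on
  synthetic cohorts should not be read as expected fMRI performance.
* Nodal/local graph metrics (local efficiency, participation coefficient)
  are out of scope.
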