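---
title: "Partially localized connectivity regression: model, importance, repeatability"
author: "connreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partially localized connectivity regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connreg)
```

## The model

A subject's resting-state functional connectivity is summarized by the
symmetric matrix of Fisher-Z transformed temporal correlations between R
parcellated brain regions. `connreg` models the ordered vector of its
strictly-upper-triangular entries — `R(R-1)/2` "edges" — with an additive
regression on region-pair characteristics:

* an intercept, absorbing global connectivity level;
* a penalized thin-plate regression spline in geographic (Euclidean
  center-to-center) distance, fit separately for same-hemisphere and
  opposite-hemisphere pairs, since proximity effects differ within and
  across hemispheres;
* a penalized spline in homotopic distance — how far one center is from the
  mirror image of the other across the mid-sagittal plane — for
  opposite-hemisphere pairs only (same-hemisphere pairs cannot be
  symmetrically opposite, so no such term exists for them);
* an unpenalized 0/1 indicator per region, flagging that the region is one
  of the pair's endpoints;
* an unpenalized indicator per network cell `(k, k')`, `k ≤ k'`: with K
  functional networks there are K intra-network and K(K-1)/2 inter-network
  cells, and every edge lies in exactly one.

Each scan (subject × session) is fit separately; nothing is pooled. The
model assumes edges are exchangeable given their covariates, additivity of
the covariate effects, and homoskedastic Gaussian edge noise. The same fit
can be read as a matrix regression: the coefficients minimize the Frobenius
norm of the residual connectivity matrix with zeroed diagonal
(`matrixRegressionCheck()` verifies the equivalence by direct minimization
on small instances).

## Edge construction

`correlationMatrix()` is plain Pearson correlation of the column time
series (at least 3 time points, no constant series; no detrending,
filtering or scrubbing is applied — preprocessing is out of scope).
`fisherZ()` is `atanh` with `|r|` clipped at `1 - 1e-7` under a warning: a
perfectly correlated pair would otherwise contribute an infinite edge and
poison every Euclidean distance downstream. The edge order — upper
triangle, row-major, regions ascending by id — is part of the file contract
so that distances between subjects' edge vectors are well defined. All
`j < j'` pairs are included; no near-diagonal or within-region exclusions.

## Design assembly and rank reduction

Smooth bases come from low-rank thin plate regression splines
(`mgcv::smoothCon`), dimension 10 per smooth by default, with the
sum-to-zero constraint absorbed so each basis is centered over the edges it
applies to; rows outside a smooth's hemisphere mask are exactly zero. After
centering, the penalty null space holds only the linear trend, so an
infinitely penalized smooth degenerates to a straight line rather than
vanishing. If a masked covariate has fewer distinct values than the basis
dimension the dimension is reduced with a warning; fewer than three
distinct values is an error.

The indicator blocks are exactly collinear with the intercept: region rows
sum to 2, network rows to 1. When both blocks are present there are K
further dependencies — summing the region indicators over the members of
network k reproduces twice the `(k,k)` column plus the `(k,·)` inter
columns — for `K + 1` in total. Reduction is deterministic: the last region
indicator and the `(K,K)` network cell are dropped first (the two canonical
dependencies), then a greedy forward rank scan over the remaining columns
in their canonical order removes whatever dependencies remain (the `K - 1`
residual network dependencies in the full model, empty network cells in
small parcellations, and similar degeneracies). Every removal is recorded
with a reason in `droppedColumns()`. Columns are unit-normalized for the
rank test only (tolerance 1e-9), so indicator and smooth columns are
compared on one scale. Identical inputs always produce bit-identical
designs.

## Fitting

With penalties active, the fit is penalized least squares with Gaussian
family and identity link; smoothing parameters are selected by REML
(default) or GCV via `mgcv::gam` with the assembled design passed as a
parametric block carrying its penalty matrices. With
`penaltySelection = "none"` the fit is ordinary least squares, which is the
mode used wherever exact nesting or closed-form oracles are wanted.
Indicator columns are never penalized. Consequently residuals are
orthogonal to them, which yields the region-mean property: for every
region — including any dropped indicator, which lies in the span of the
retained columns — the average fitted value over that region's edges equals
its average observed connectivity, to solver precision, penalized or not.

R² is the unadjusted `1 - RSS/TSS`. Unadjusted on purpose: the importance
decomposition below partitions exactly this quantity, and an adjusted
version would break its additivity.

## Group-wise importance

The LMG relative importance of a covariate group is its average increase in
R² over all orders in which the groups could enter the model. It is
computed with Shapley subset weights — `2^G` subset refits instead of
`G!·G` — which is algebraically identical to enumerating orderings (the
tests verify this against a literal 24-ordering enumeration for G = 4).
Contributions telescope, so they sum to the full model's R² exactly, no
matter how each subset R² was produced.

Two interpretation choices were genuinely open:

* **Subset models re-select their smoothing parameters** rather than
  freezing those of the full model. Adding a group means refitting the
  model a practitioner would actually fit; freezing would privilege the
  full model's effective degrees of freedom.
* **Per-predictor relative importance divides by nominal group sizes** —
  geography 2, homotopy 1, networks K(K+1)/2, regions R, intra K, inter
  K(K-1)/2 — not by post-reduction column counts. Columns dropped for rank
  still represent predictors of the named type, and the nominal convention
  reproduces the published style of per-predictor scores. The reported
  score is `100 × PVE / size`.

The `intra_inter` variant splits the network block into intra- and
inter-network groups (G = 4 with geography and homotopy) while spanning
exactly the same column space as the merged model, so the same total gets
partitioned.

## Discriminability

For n subjects measured at T sessions, sample discriminability is the
proportion of comparisons in which two measurements of the same subject are
strictly closer than a measurement of that subject and one of another
subject, over all `n(n-1)T²(T-1)` valid comparisons. The inequality is kept
strict, exactly as the estimator is defined: ties contribute nothing to the
numerator and are counted separately (`tieCount()`), so degenerate inputs
are visible rather than silently flattering. On the four-point scalar toy
(subject 1: 0, 5; subject 2: 3, 4) exhaustive enumeration gives 3 strict
successes, 1 tie, 4 failures — δ̂ = 3/8 — and the implementation is tested
to agree with that enumeration term by term.

Ordered measurements (edge vectors, fitted-value vectors) use Euclidean
distance; edge distributions use the 2-Wasserstein distance, which for
equal-size one-dimensional samples is the Euclidean distance between sorted
value vectors. Fitted values, not coefficient vectors, are the model-based
measurement: they are fixed in dimension across model variants and
unit-free, so all approaches are compared in the same space. (The
Mahalanobis-flavored coefficient-space variant is deliberately not
implemented.)

The permutation reference re-pairs each subject's session-1 measurement
with the session-2 measurement of a uniformly random subject — fixed points
allowed, 1000 permutations by default, seeded — and re-evaluates the
estimator each time. Random re-pairing destroys within-subject signal, so
the mean settles at 0.50 for continuous data; the summary reports the mean
and the central 95% empirical interval (an interval convention, not a test).

## The synthetic generator

`simulateEdges()` draws data from the same additive structure the model
fits, plus the one ingredient real data have and the covariates cannot
carry: a subject-specific edge-level effect, stable across sessions. Per
subject, every coefficient group is perturbed around its population value
(Gaussian), and per session i.i.d. Gaussian noise is added:

| parameter | default | meaning |
|---|---|---|
| `R`, `K` | 20, 4 | mirror-paired regions, networks |
| `beta0` | 0.3 | mean Fisher-Z connectivity |
| `geogAmp`, `geogScale` | 0.6, 40 mm | distance decay `a·exp(-d/τ)` |
| `homotAmp`, `homotScale` | 0.4, 30 mm | homotopy effect, opposite pairs |
| `regionSd`, `networkSd` | 0.1, 0.15 | population effect spreads |
| `subjectInterceptSd`, `subjectAmpSd` | 0.05, 0.1 | subject-level perturbations |
| `subjectRegionSd`, `subjectNetworkSd` | 0.05, 0.05 | subject-level perturbations |
| `subjectEdgeSd` | 0.1 | subject-private edge structure |
| `sessionSd` | 0.1 | per-scan noise |

Magnitudes sit in the range typical of Fisher-Z resting-state edges (bulk
of values within ±1, mean positive, distance decay over a few centimeters).
The truth functions are smooth exponentials, deliberately outside the
spline family, so fitted smooths must approximate rather than memorize.
Parcellations are sampled uniformly in a right-hemisphere box of roughly
adult-brain extent (lateral 8–65 mm, posterior–anterior −90–55 mm, axial
−45–65 mm) and mirrored, giving every region an exact homotopic partner;
networks are assigned mirror-symmetrically at random.

The generator stores full ground truth (every per-subject coefficient, the
noiseless covariate signal, the total signal) in the experiment metadata,
and `truePVE()` converts the realized variance budget into the population
R² a correctly specified model would attain:
`var(covariate signal) / (var(covariate signal) + subjectEdgeSd² +
sessionSd²)`.

What the generator does **not** emulate: temporal autocorrelation, motion
and physiological artifacts, heavy-tailed or skewed edge distributions,
spatially contiguous networks, inter-subject misregistration as an explicit
spatial process. Passing tests therefore establish correctness of the
statistical machinery under the model's own assumptions — not that real
fMRI obeys them.

## Validation experiment sizes

The test suite's simulation studies use sizes chosen to make their
conclusions sharp at desk scale:

* *Parameter and PVE recovery*: 50 subjects, R = 40, K = 4, session noise
  0.1. Network effects are checked through estimable contrasts — weight
  vectors with zero total weight and zero endpoint-weighted sum within each
  network, the combinations untouched by the indicator collinearities —
  with unbiasedness required within three Monte-Carlo standard errors.
  Mean fitted R² is required to match the variance-budget PVE within 0.03;
  the fitted value carries optimism of order `(1 - PVE)·edf/n ≈ 0.015` at
  these sizes, which the band accommodates without hiding real
  misspecification.
* *Summary ordering*: 20 replicates of 8 subjects × 2 sessions, R = 20,
  with session noise 0.6, subject edge-level sd 0.4, and subject
  region/network sds 0.15. The noise is set high enough that no summary
  saturates at δ̂ = 1 and the ordering — edge-at-a-time above the full
  model above the reference model, with the reference model comparable to
  the edge distribution — is actually informative; the strong edge-level
  effect is what puts edge-at-a-time at the top, mirroring the
  subject-private structure that covariates cannot explain in real data.
* *Permutation null*: 100 subjects × 2 sessions, 200 permutations, mean
  required within 0.01 of 0.50.

## Numerical choices and degenerate inputs

* Correlation clipping at `|r| = 1 - 1e-7`, warned, never silent.
* Rank decisions at tolerance 1e-9 on unit-normalized columns; drops are
  deterministic and recorded.
* Ties in discriminability count zero and are reported.
* Constant observed vectors make R² an error, not an NaN; constant
  covariates on a smooth's mask are an error; too-few distinct values
  shrink the basis with a warning.
* Every stochastic routine takes an explicit seed; rebuilding a design or
  refitting identical input is bit-identical.

## Conventions adopted where sources are silent

* Hemisphere labels in a parcellation file are authoritative; a lateral
  coordinate whose sign contradicts the label warns but does not fail, and
  exactly-midline regions (first coordinate 0) are consistent with either
  label.
* All region pairs enter the edge vector; there are no proximity-based
  exclusions.
* The drop set for full rank (canonical drops plus greedy scan in column
  order) is a convention; any other choice spans the same space and yields
  the same fitted values, importance values and discriminability.
* The permutation scheme allows fixed points; with 100 subjects the
  resulting upward drift of the null mean is far below the reporting
  precision.

## Limitations

Inference on individual coefficients (standard errors, p-values),
group-level mixed-effects comparisons, partial correlations and tangent
metrics, voxel-level designs, and any fMRI preprocessing or atlas handling
are out of scope. Importance is defined at the group level only;
per-individual-predictor LMG over hundreds of indicators would require
astronomically many refits and is intentionally absent.
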