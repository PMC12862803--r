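---
title: "Instance-based modeling of molecular cluster energies with molknn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance-based modeling of molecular cluster energies with molknn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molknn)
```

## The problem

Quantum-chemical (QC) calculations of electronic binding energies for
molecular clusters — for example the sulfuric-acid–water clusters that seed
atmospheric new-particle formation — are accurate but expensive, scaling
steeply with system size. Given a database of cluster structures with QC
labels, an instance-based regression model can interpolate those labels to
new structures at a tiny fraction of the cost. `molknn` implements a family
of such models around one central idea: *k*-nearest-neighbor (k-NN)
regression becomes competitive with kernel ridge regression (KRR) once it is
given a chemically meaningful distance, while remaining orders of magnitude
cheaper and directly interpretable through its neighbor sets.

The package covers the full pipeline: structures are read from multi-frame
XYZ files (labels as `key=value` tokens on the comment line), converted to
numeric descriptors, and fed to one of five model families. A synthetic
cluster generator provides two-level labeled data so every stage is testable
without external databases.

## Models

**KRR.** With a positive-definite kernel $k(\mathbf{x}, \mathbf{x}')$ the
prediction is $f(\mathbf{x}) = \sum_i \alpha_i k(\mathbf{x}_i, \mathbf{x})$
with $\boldsymbol\alpha = (K + \lambda I)^{-1}\mathbf{y}$. We solve the
symmetric system by Cholesky factorization with a single
$10^{-10}\,\mathrm{tr}(K)/n$ jitter retry; a solve whose residual exceeds
$10^{-8}\lVert\mathbf{y}\rVert$ is treated as singular and the error message
recommends a positive ridge. Two kernels are provided: a global RBF
$\exp(-\lVert\mathbf{a}-\mathbf{b}\rVert^2/2\sigma^2)$ on fixed-length
descriptor vectors, and an *extensive* kernel
$\sum_{\alpha\in i}\sum_{\beta\in j}[Z_\alpha = Z_\beta]\,
\exp(-\lVert\mathbf{q}_\alpha-\mathbf{q}_\beta\rVert^2/2\sigma^2)$ that sums
atomic-environment kernels and therefore grows with system size, matching
extensive targets such as binding energies. Atomic kernels are restricted to
same-element pairs by default, the standard practice for
atomic-decomposition kernels.

**k-NN under three distances.** The k-NN prediction is a weighted average of
the $k$ nearest training labels, with uniform or reciprocal-distance weights
($w_i = d_i^{-1}/\sum_l d_l^{-1}$; if a distance is exactly zero the
prediction is the mean of the zero-distance labels, the limit of reciprocal
weighting). Ties in distance are broken by ascending training index so all
results are deterministic. The three distances are

* plain Euclidean distance between global descriptor vectors;
* the **kernel-induced distance**
  $d(\mathbf{x},\mathbf{x}') = \sqrt{k(\mathbf{x},\mathbf{x}) +
  k(\mathbf{x}',\mathbf{x}') - 2k(\mathbf{x},\mathbf{x}')}$, the Euclidean
  distance in the kernel's feature space — a valid pseudometric whenever
  $k$ is positive definite (arguments under the root more negative than
  $-10^{-9}$ relative are treated as evidence of a non-PSD kernel and raise
  an error; smaller negativity is clamped to zero);
* a **learned Mahalanobis metric**
  $d_M(\mathbf{x},\mathbf{x}') = \lVert A(\mathbf{x}-\mathbf{x}')\rVert$
  from MLKR (below).

**MLKR.** Metric Learning for Kernel Regression minimizes the leave-one-out
kernel-regression squared error
$\mathcal{L}(A) = \sum_i \big(y_i - \hat y_i\big)^2$, where
$\hat y_i = \sum_{j\ne i} y_j k_{ij} / \sum_{j\ne i} k_{ij}$ and
$k_{ij} = \exp(-d_M(\mathbf{x}_i,\mathbf{x}_j)^2/\sigma^2)$. Writing
$M = A^\top A$ keeps the metric positive semidefinite without constraints,
and capping the number of rows of $A$ (rank limit, default 50) bounds both
cost and model capacity, similar in spirit to a PCA truncation. The
implemented analytic gradient is the exact derivative of this objective,

$$\frac{\partial\mathcal{L}}{\partial A} = \frac{4}{\sigma^2}\,A
\sum_{i\ne j} e_i\,(\hat y_i - y_j)\,P_{ij}\,
(\mathbf{x}_i-\mathbf{x}_j)(\mathbf{x}_i-\mathbf{x}_j)^\top,$$

with $e_i = \hat y_i - y_i$ and $P_{ij} = k_{ij}/\sum_{l \ne i} k_{il}$; the
test suite verifies it against central finite differences to a relative
$10^{-5}$. A note on conventions: some write-ups of MLKR print the kernel as
$\exp(-d_M/\sigma^2)$ with $d_M$ already carrying a square root. We default
to the squared-distance (standard RBF) form, which is the differentiable
choice consistent with the gradient above; `form = "printed"` switches the
loss and gradient to the literal unsquared form for comparison.

Numerical choices in `mlkr_fit()`:

* features are standardized to zero mean and unit variance, and $\sigma$ is
  then fixed at 1 — its scale is absorbable into $A$, so fitting both would
  be unidentifiable;
* $A$ is initialized from the top-$p$ principal directions scaled to unit
  component variance (deterministic, with a fixed sign convention), not from
  random noise;
* the row-wise minimal squared distance is subtracted before exponentiation
  in the LOO-KR ratio, which leaves the ratio unchanged but prevents the
  weights of distant points from underflowing to an all-zero row; should a
  row still underflow, that point falls back to its nearest neighbor's
  label rather than producing NaN;
* optimization is L-BFGS with at most 200 iterations and relative
  loss-change tolerance $10^{-6}$; with more than `subsample_cap` (default
  25,000) points the objective is evaluated on a seeded subsample without
  replacement, and the learned metric is then applied to all data.

**Kernel regression with the learned metric** is included as a comparator:
the prediction weights are a softmax of distance over *all* training points,
$w_j = k(d_M(\mathbf{x},\mathbf{x}_j))/\sum_l k(d_M(\mathbf{x},\mathbf{x}_l))$,
the same estimator MLKR optimizes internally. Comparing it with MLKR-metric
k-NN isolates what the hard neighbor cutoff contributes.

**Delta-learning.** When two label levels are available (an expensive
high-level and a cheap low-level method), models are trained on the residual
$y_\mathrm{high} - y_\mathrm{low}$ and predict
$y_\mathrm{low}(\mathbf{x}) + \hat f(\mathbf{x})$. The residual is smoother
and smaller in range than the raw label, so the same model reaches lower
error at the same training size.

## Descriptors

Three descriptor families are implemented behind one schema rule: the
schema (padding size, bag sizes, element set) is always derived from the
*whole* dataset before any train/test split, so train and test vectors
align.

* **Sorted Coulomb matrix**: $M_{ii} = 0.5\,Z_i^{2.4}$,
  $M_{ij} = Z_iZ_j/r_{ij}$ with $r$ in Bohr (1 Å = 1.8897259886 Bohr,
  the convention of the descriptor literature); rows/columns sorted by
  descending row norm for atom-order invariance, zero-padded, upper
  triangle flattened.
* **Bag of bonds**: the same pair terms grouped per unordered element pair,
  sorted descending within each bag, zero-padded, bags concatenated in
  lexicographic order.
* **Smeared 2-/3-body local descriptor**: per atom, Gaussian-smeared radial
  histograms of neighbor distances (one block per neighbor element) and
  Gaussian-smeared angular histograms of neighbor-pair angles (one block per
  unordered element pair), all damped by the smooth cutoff
  $f_\mathrm{cut}(r) = \tfrac12(1+\cos(\pi r/r_c))$ for $r < r_c$. Defaults:
  cutoff 8 Å, 24 radial bins with width equal to the bin spacing, 12 angular
  bins on $[0,\pi]$ — a resolution similar to discretized 2-/3-body
  descriptors in the literature at modest dimensionality. Summing the atomic
  rows (`globalize()`) yields a fixed-length global vector. This implements
  the descriptor *family*; codes that compute specific published variants
  can inject their vectors through `import_representations()`, and all
  models downstream are descriptor-agnostic.

All three are invariant to atom ordering, rigid rotations and translations
(property-tested), and the local descriptor's entries are non-negative and
bounded by the neighbor count.

## Choosing k, and uncertainty from neighbor sets

The dominant k-NN hyperparameter is $k$. `tune_k_loo()` scores an entire
grid from one distance-matrix pass using the $(k{+}1)$-neighbor identity:
for uniform weights the leave-one-out prediction at $k$ equals
$\big((k{+}1)f_{k+1}(\mathbf{x}_i) - y_i\big)/k$, where $f_{k+1}$ is the
self-including $(k{+}1)$-neighbor mean. The suite verifies this identity to
$10^{-12}$ against explicit re-queries. For reciprocal weights the self
point (distance zero) would degenerate the weights, so it is dropped and the
next $k$ neighbors are used. In practice the error curve is flat for
$5 \le k \le 15$ on smooth, well-sampled data, and $k = 10$ is the package
default when tuning is skipped.

Because a k-NN prediction is a statistic of a concrete neighbor set, other
statistics of the same set are free: `neighbor_quantiles()` returns
empirical percentiles of the neighbor labels as a per-item uncertainty
band, and `calibration_curve()` compares estimated percentiles against the
observed fraction of true labels falling below them. One estimator subtlety
matters at small $k$: the mode-based linear-interpolation quantile (R type
7, the package default, e.g. labels $\{1,\dots,5\}$ give 2.0 at the 25th
percentile) has expected coverage $((k-1)p+1)/(k+1)$ rather than $p$ — at
$k = 31$ its 10th percentile is exceeded by about 12.5% of future draws, a
bias large enough to dominate the binomial noise of a 2000-item test set.
For calibration work `neighbor_quantiles(..., "coverage_unbiased")`
therefore uses the $p(k{+}1)$ interpolation rule (type 6), whose expected
coverage is exactly $p$; with it the observed deciles track the nominal ones
within three binomial standard errors in the calibration test.

## The synthetic data generator

`generator_config()` + `synthetic_dataset()` emulate an atmospheric-cluster
database closely enough to exercise every pipeline stage:

* clusters are assembled from a library of *rigid, stylized* units — an
  S-centered 5-atom "SA" unit, a bent 3-atom "W" unit, a pyramidal 4-atom
  "AM" unit. The shapes are schematic, not chemically accurate, and are
  declared as such;
* compositions such as `(SA)2(W)3` are drawn from a configurable
  distribution whose default spans `(SA)1(W)1` through `(SA)4(W)5`; units
  are placed at random positions and orientations in a 9 Å box under a
  2.2 Å inter-unit minimum distance (rejection sampling, 1000 attempts per
  unit), then jittered with 0.05 Å Gaussian noise;
* the high-level label is a sum of per-element reference energies and Morse
  pair energies $D_e[(1-e^{-\alpha(r-r_e)})^2 - 1]$ within 12 Å, with
  $D_e \in [2, 8]$ kcal/mol, $r_e \in [1.5, 3.0]$ Å and soft widths
  $\alpha \approx 1$ Å$^{-1}$ — a bounded, smooth potential whose soft wall
  keeps intra-unit contacts off the repulsive regime, so cluster energies
  are negative and decrease (become more strongly bound) with cluster size,
  as binding energies do;
* the low-level label evaluates the same functional with Morse parameters
  relatively perturbed by 8%, plus a smooth per-composition offset and
  0.5 kcal/mol Gaussian noise. The residual is therefore *structured and
  learnable*, as delta-learning assumes, and its variance is a few percent
  of the raw label variance.

What the generator deliberately does **not** reproduce: real QC energetics,
conformer ensembles, anharmonic unit distortions, or the descriptor
degeneracies of real chemistries. Tests passing on this data demonstrate
that the algorithms are implemented correctly and that their qualitative
orderings (delta beats direct; learned metric beats raw Euclidean;
extrapolating to the largest held-out composition is harder than
interpolating) emerge for the right structural reasons — they do not certify
accuracy numbers on any real database.

## Evaluation harness

`cross_validate()` performs 5-fold cross-validation with a fixed-size test
fold: the fold is held out, and training sets of each requested size are
seeded subsamples of the remaining 80%. Learning-curve subsamples are drawn
independently per size (nested sampling would be a valid alternative; we
chose independence so each size is an unbiased draw). All randomness flows
from one master seed through named substreams, so every result is exactly
reproducible. `extrapolation_split()` instead holds out every structure of
one composition — typically the largest — to probe extrapolation.
`tune_krr_hyperparams()` grid-searches $(\sigma, \lambda)$ on a 4000/1000
split (capped 4:1 at small n; ties resolve toward the more regularized
model), and `tune_knn_k()` runs a 5-fold CV search over $k$ on a subsample
of at most 5000 items. Timings are recorded in the result tables but never
asserted — they are hardware facts, not contracts.

Default widths use the median-pairwise-distance heuristic; the default ridge
is $\lambda = 10^{-4}$, since with smooth kernels and a few hundred points
smaller penalties leave the Gram matrix numerically singular and the
interpolant unstable.

The acceptance checks in the test suite use deliberately desk-scale problem
sizes — 500–1000 synthetic clusters, feature dimensions of a few hundred,
10 seeds per comparison, single evaluation folds for the 5-model learning
curves — chosen so the full suite replicates the qualitative findings in a
few minutes on one CPU.

## Neighbor search backends

The brute-force backend computes all distances; the tree backend is a
KD-tree (median split on the widest dimension, leaf size 16) whose pruning
rule keeps equal-distance boundary points, so its results — including the
ascending-index tie-break — are bit-identical to brute force. The
kernel-induced mode has no explicit coordinates to build a tree on, so it
precomputes dense train–train and test–train distances and always searches
exhaustively; correctness over speed was the design choice there.

## Known limitations

* MLKR cost is $O(n^2 d\,p)$ per gradient evaluation in dense R linear
  algebra; the subsample cap is the intended control for large n.
* The KD-tree is written in plain R; it exists for exactness-tested
  algorithmic completeness, and on high-dimensional descriptors (where
  pruning rarely triggers) brute force is usually faster.
* No descriptor gradients are provided, so no force learning.
* The extensive kernel materializes dense atomic blocks; very large
  structures should use blocked evaluation and generous memory.
* Single-composition datasets make `extrapolation_split()` impossible by
  construction (it errors rather than returning an empty test set).
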