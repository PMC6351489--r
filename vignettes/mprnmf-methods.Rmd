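---
title: "Predicting lncRNA functions by multi-view partially regularized NMF"
author: "MPrNMF package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA functions by multi-view partially regularized NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MPrNMF)
```

## The model

Long non-coding RNAs are sparsely annotated in the Gene Ontology, while
protein-coding genes are richly annotated. The idea behind this package
is to transfer annotation signal from genes to lncRNAs through several
heterogeneous lncRNA–gene association *views* without first fusing the
views into one network.

All matrices share one index convention: entities are ordered lncRNAs
first, then genes, both in the order introduced by the input files. The
binary annotation matrix $X \in \{0,1\}^{n_o \times (n_l + n_g)}$ holds
the known term–entity associations of both classes. Each view $i$
contributes a nonnegative association matrix
$Y_i \in \mathbb{R}^{n_l \times n_g}$ — here thresholded Pearson
co-expression and disease-set Jaccard similarity — and its coupling
operator
$$C_i^{*} = \begin{pmatrix} 0 & Y_i \\ Y_i' & 0\end{pmatrix},$$
the bi-colored matrix of the view with the within-class blocks zeroed.
The factorization solves

$$\min_{B, F \ge 0}\; J \;=\; \lVert X - BF\rVert_F^2
  \;-\; \alpha \sum_i \operatorname{tr}(F C_i^{*} F')
  \quad \text{s.t.}\quad \mathbf{1}'F = \mathbf{1}' ,$$

with basis $B \in \mathbb{R}_{\ge0}^{n_o \times k}$ and features
$F = [F_l \,|\, F_g] \in \mathbb{R}_{\ge0}^{k \times (n_l+n_g)}$, each
entity column of $F$ constrained to the $k$-simplex (the $\ell_1$
constraint that induces sparse, comparable feature profiles). Because
$\operatorname{tr}(F C_i^{*} F') = 2\operatorname{tr}(F_l Y_i F_g')$,
the trace term rewards agreement between the latent features of
associated lncRNA–gene pairs, view by view — the *partial*
regularization: only the cross-class associations regularize $F$; the
within-class networks (PPI, lncRNA co-expression) enter the baselines
but not the factorization objective.

A note on the sign of the regularizer: a *penalty*
$+\alpha\sum_i\operatorname{tr}(FC_i^*F')$ would push coupled features
*apart* (the trace is nonnegative-definite in no useful sense here; its
maximizer aligns coupled columns), which contradicts both the stated
intent that $F$ reflect the association structure and the multiplicative
update below, whose fixed point places the $\alpha$ term in the
numerator (the attractive part of the gradient). The package therefore
subtracts the trace term, and documents this prominently in
`mprObjective()`.

## Optimization

The objective is non-convex jointly but multiplicatively updatable in
each factor (Karush–Kuhn–Tucker conditions of the Lagrangian):

$$B \leftarrow B \odot \frac{[XF']}{[BFF']}, \qquad
  F \leftarrow F \odot
  \frac{[B'X + \alpha\sum_i FC_i^{*}]}{[B'BF]},$$

followed by renormalization of every entity column of $F$ onto the
simplex, which absorbs the Lagrange multiplier of the $\ell_1$
constraint. Numerical choices:

* **Orientation of the update ratios.** The numerator is the negative
  part of the gradient (standard Lee–Seung orientation); with this
  orientation an exact factorization $X = BF$ with column-stochastic
  $F$ is an exact fixed point of both updates at $\alpha = 0$, which the
  test suite asserts to $10^{-10}$.
* **Damped variant.** An optional `variant = "sqrt"` update multiplies
  by the elementwise square root of the same ratio (a half-step in the
  log domain), useful when updates overshoot; the default is the
  standard step.
* **Epsilon guard.** Denominators carry $+10^{-12}$; zero entries of
  $B$ and $F$ stay zero (multiplicative invariance). A feature column
  driven entirely to zero is reset to uniform $1/k$ with a warning.
* **Initialization and determinism.** $B, F \sim U(0,1)$ under an
  explicit seed, $F$ column-normalized; identical seeds reproduce
  bitwise-identical trajectories. Because the updates find local optima,
  `mprnmf(..., restarts = n)` fits $n$ seeded initializations (seeds
  derived deterministically from the main seed) and keeps the lowest
  final objective — best-of-restarts is standard NMF practice and is
  used throughout the package's experiments with `restarts = 3`.
* **Termination.** At most `iterations` rounds (default 100) with early stop when
  $|\Delta J| / |J| < 10^{-6}$. The objective is recorded at
  initialization and after every completed iteration.
* **Monotonicity.** At $\alpha = 0$ the classical multiplicative-update
  argument applies and $J$ is non-increasing (asserted within
  $10^{-9}$); the column renormalization can in principle break strict
  monotonicity, so for $\alpha > 0$ the package tracks (and the tests
  assert) only that the objective declines over the whole run in at
  least 19 of 20 seeded fits.

Predicted lncRNA–term scores are $B F_l$, min–max scaled to $[0,1]$ so a
common threshold grid applies. (A notation sometimes used for this
step divides $B = [B_l\, B_g]$ and writes the prediction as
"$B_l F_l$", but $B$ is ontology-by-rank and has no lncRNA/gene rows;
$B F_l$ is the only shape-consistent reading and is what the package
implements.)

## Choosing the tunables

* **Rank k** is selected by factorization instability: for each
  candidate k, $\tau$ random restarts (default $\tau = 10$) are fitted
  and
  $$\Upsilon(k) = \tfrac{2}{\tau(\tau-1)}\sum_{i<j}
  \mathrm{diss}(B_i, B_j), \qquad
  \mathrm{diss}(B_1,B_2) = \tfrac{1}{2k}\big(2k - \textstyle\sum_j \max
  H_{\cdot j} - \sum_i \max H_{i\cdot}\big)$$
  with $H$ the matrix of Pearson correlations between basis columns
  ("cross correlation" is read as Pearson correlation; zero-variance
  columns correlate 0). $\mathrm{diss}$ is zero when the bases agree up
  to column permutation and positive rescaling, and $\approx 1$ for
  mutually uncorrelated bases. The selected k minimizes $\Upsilon$
  (ties toward the smaller k). The default candidate grid is 40–64 in
  steps of 4, a range suited to benchmark-scale data; the synthetic
  experiments
  use 2–10 in steps of 2 around the planted rank.
* **Regularization weight α.** The scale of the trace term depends on
  the density of the views relative to $X$: on the package's synthetic
  instances $\sum_{l,g} Y_i[l,g]$ is comparable to
  $\lVert X\rVert_F^2$, so weights near 1 let the regularizer dominate
  and collapse every feature column onto a single component (the trace
  is maximized by a rank-one $F$). α is therefore not portable across
  data scales and is chosen by the Fmax sensitivity sweep
  (`sweepAlpha()`) over the grid 0.1–1.9 in steps of 0.2, evaluating
  held-out annotation recovery; on the synthetic study conditions the
  sweep lands at the low end (0.1). Sparser views relative to $X$
  support proportionally larger weights.
* **Co-expression threshold 0.5** (configurable): negative Pearson
  correlations are dropped, not absolute-valued, because the
  factorization requires nonnegative couplings; `useAbsolute = TRUE`
  exposes the alternative. Whether expression is log-transformed before
  correlation is a config flag (`logExpression`) with no default claim.
* **Evaluation.** Micro-averaged recall/precision: TP/FP/FN are summed
  over the evaluated lncRNAs *before* dividing (note the canonical
  CAFA Fmax is macro-averaged; this package micro-averages by design).
  Only lncRNAs with at least one true term
  enter evaluation. Degenerate denominators use precision = 1 when
  nothing is predicted and recall = 0 when no true terms exist, so the
  sweep is total; both conventions emit a message when triggered. The
  default threshold grid is 0–1 in steps of 0.01 on min–max-scaled
  scores; the smallest maximizing threshold is reported, with
  float-level ties (differences < $10^{-12}$) resolved toward the
  smaller threshold.

## The synthetic benchmark

`generateInstance()` plants `plantedK` latent function modules shared by
lncRNAs and genes and derives every data layer from the same hidden
grouping, emulating the joint structure the method assumes:

* **Expression**: each module owns a latent profile over 30 samples
  (enough for stable Pearson estimates at desk scale); profiles are
  constructed mutually orthogonal after centering so that at
  `noise = 0` within-module correlation is exactly 1 and cross-module
  exactly 0 — i.i.d. profiles would leak $O(n^{-1/2})$ spurious
  cross-correlation into the "exactly block-structured" regime. An
  entity's profile adds `noise` × independent Gaussian noise.
* **Diseases**: each module owns a disjoint pool of 8 diseases; a
  member carries a uniform fraction in $[1 - \mathrm{noise}/2,\, 1]$ of
  its pool (the full pool at `noise = 0`, so within-module Jaccard is
  exactly 1 and cross-module 0) plus Poisson(noise × 3) background
  diseases from a shared pool, which creates graded cross-module
  overlap at positive noise.
* **PPI**: gene pairs connect with probability 0.6 within modules and
  0.02 across — dense enough that the largest connected component spans
  nearly all genes, so the connectivity filter is exercised without
  destroying the instance.
* **Annotations**: the terms are split into `plantedK` disjoint blocks;
  every member of a module carries all of its block's terms. A fraction
  of the lncRNA positives (exactly
  $\lfloor \mathrm{fraction} \times \mathrm{positives}\rfloor$, gene
  columns untouched) is hidden from the training matrix for recovery
  experiments.

What this generator does *not* emulate: the heavy-tailed degree
distributions, annotation-depth imbalance, GO-hierarchy structure and
inter-term correlation of real databases, nor realistic class
imbalance — real benchmarks have far fewer than 100% of lncRNAs
annotated and much sparser, noisier views. Passing the held-out recovery
experiments therefore demonstrates correctness of the machinery and the
qualitative behavior of the method (view integration helps; the
planted rank is recoverable), not the Fmax levels attainable on real
data.

## Study conditions used by the experiments

The acceptance script and the corresponding tests run at a fixed desk
scale chosen to finish in minutes on one CPU while leaving the planted
structure non-trivial: $n_l = 50$, $n_g = 150$, $n_o = 40$, 6 planted
modules, noise 0.1, 20% of lncRNA annotations masked, rank grid
$\{2,4,6,8,10\}$ with $\tau = 10$, three restarts per fit, 100
iterations. Recovery is scored by threshold-swept Fmax over the hidden
annotations (training positives are zeroed in the score matrix first,
so only novel associations count) and by the Mann–Whitney AUROC of
masked pairs against true non-associations.

## Baselines

The comparison predictors are implemented exactly from their stated
objective functions:

* `labelPropagation()`: minimize
  $\theta\,\mathrm{tr}(\hat X L \hat X') + (1-\theta)\lVert\hat X - X\rVert^2$
  over one network's normalized Laplacian; closed form
  $\hat X = (1-\theta)X(\theta L + (1-\theta)I)^{-1}$ and a contractive
  fixed-point iteration are both provided and must agree.
* `bicoloredLabelPropagation()`: the same objective on the bi-colored
  matrix $C = [[W_l, Y],[Y', W_g]]$, through which gene annotations
  reach lncRNA columns.
* `dualLabelPropagation()`: the two entity classes are smoothed
  independently
  ($\hat X_l = X_l(\gamma L_l + I)^{-1}$,
  $\hat X_g = X_g(\beta L_g + I)^{-1}$); the formulation contains no
  lncRNA–gene coupling term — the two classes decouple — which the
  documentation points out to users.
* `katzScores()` / `katzPredict()`: truncated path-count series
  $S = \sum_{p\le P}\beta^p C^p$; term predictions apply the
  lncRNA–gene block of $S$ to the gene annotations
  ($X_g S_{lg}'$ — there is no canonical convention for this step, so
  the choice is documented). Defaults
  $\theta = 0.5,\ \beta = \gamma = 0.5,\ \beta_{\mathrm{KATZ}} = 0.01,
  P = 3$ are conventional.

## Known limitations

* The regularizer scale ties α to the data; users must sweep α on their
  own data rather than reuse a value from another dataset.
* No GO-hierarchy (true-path) propagation is performed on the
  annotations; annotation matrices are used exactly as provided.
* More than two views are supported structurally (any list of
  couplings) but all views share one α; no per-view weight learning.
* The dense matrix implementation targets desk-scale and
  benchmark-scale problems (up to a few thousand entities), not
  genome-scale sparse runs.
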