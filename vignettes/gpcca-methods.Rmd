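---
title: "Generalized probabilistic CCA: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized probabilistic CCA: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcca)
```

## The model

`gpcca` integrates $R \ge 2$ data modalities — feature-by-sample numeric
matrices $\mathbf{X}^{(r)} \in \mathbb{R}^{m_r \times n}$ measured on the same
$n$ samples — through a shared latent factor model. Stacking the modalities
into $\mathbf{X} \in \mathbb{R}^{m \times n}$ with $m = \sum_r m_r$, each
sample $k$ is modeled as

$$
\mathbf{x}_k = \mathbf{W}\,\mathbf{z}_k + \boldsymbol\mu + \boldsymbol\epsilon_k,
\qquad
\mathbf{z}_k \sim \mathcal{N}_d(\mathbf{0}, \mathbf{I}),
\qquad
\boldsymbol\epsilon_k \sim \mathcal{N}_m(\mathbf{0}, \boldsymbol\Psi),
$$

where $\mathbf{W} \in \mathbb{R}^{m \times d}$ holds the loadings of all
modalities on a common $d$-dimensional latent space
($1 \le d \le \min_r m_r$), and the error covariance $\boldsymbol\Psi$ is
**block diagonal**: residual correlations are allowed between features of the
same modality but not across modalities. This sits between a strictly
diagonal error model (as in probabilistic PCA, which ignores residual
feature-feature correlation) and an unrestricted covariance (unidentifiable
and overfit-prone at realistic $m/n$). All cross-modality covariance must
therefore be carried by the shared factors, which is exactly what makes the
latent embedding $\mathrm{E}(\mathbf{z}_k \mid \mathbf{x}_k)$ a useful
integrated representation for clustering: signal confined to a single
modality can be absorbed by that modality's error block, while structure
shared across modalities cannot. A `covariance = "diagonal"` mode restricts
every block to its diagonal, recovering factor-analysis behavior.

## Estimation with missing data

Parameters $\Theta = (\mathbf{W}, \boldsymbol\mu, \boldsymbol\Psi)$ are
estimated by EM under the missing-at-random assumption. An indicator matrix
$\mathbf{O}$ marks the observed entries; for each subject only the observed
sub-vector $\tilde{\mathbf{x}}_k$, sub-loadings $\tilde{\mathbf{W}}_k$,
sub-mean and observed sub-blocks $\tilde{\boldsymbol\Psi}_k$ enter the
computation, so entry-wise missingness and wholly missing modalities are
handled by the same code path. The per-subject posterior uses the $d \times d$
Woodbury matrix

$$
\tilde{\mathbf{M}}_k =
\left(\mathbf{I} + \tilde{\mathbf{W}}_k^\top \tilde{\boldsymbol\Psi}_k^{-1}
\tilde{\mathbf{W}}_k\right)^{-1},
$$

so no $m \times m$ matrix is ever inverted. The E-step computes
$\mathrm{E}(\mathbf{z}_k \mid \tilde{\mathbf{x}}_k)$,
$\mathrm{E}(\mathbf{z}_k\mathbf{z}_k^\top \mid \tilde{\mathbf{x}}_k) =
\tilde{\mathbf{M}}_k + \mathrm{E}(\mathbf{z}_k)\mathrm{E}(\mathbf{z}_k)^\top$,
the completed data values
$\mathrm{E}(X_{ik} \mid \tilde{\mathbf{x}}_k) = \mathbf{W}_{i\cdot}
\mathrm{E}(\mathbf{z}_k \mid \tilde{\mathbf{x}}_k) + \mu_i$ for unobserved
entries, the cross-moments, and the within-block second moments; the M-step
updates $\boldsymbol\mu$, $\mathbf{W}$ and the blocks of $\boldsymbol\Psi$
from these sufficient statistics, with all off-block second moments discarded
(they never enter the block-diagonal update, so they are never computed —
memory stays at $O(\sum_r m_r^2)$ rather than $O(m^2)$).

Implementation notes that matter for performance:

* Per iteration, each full error block is inverted once and
  $\boldsymbol\Psi_r^{-1}\mathbf{W}_r$ is cached; subjects observing a full
  block reuse the cache. Subjects with a partially observed block use the
  Schur-complement identity
  $\tilde\Psi_{oo}^{-1} = P_{oo} - P_{om}P_{mm}^{-1}P_{mo}$ on the cached
  inverse $P = \boldsymbol\Psi_r^{-1}$, so per-subject cost scales with the
  number of *missing* rows. Results are independent of caching; the test
  suite verifies this contract against a direct factorization path and
  against a dense brute-force oracle.
* Rank-one accumulations over subjects are deferred and executed as single
  BLAS-3 products at the end of each E-step pass.
* With a complete observation mask every subject hits the cached full-block
  path, which is the simplified complete-data algorithm: one shared
  factorization per iteration.

### The update schedule

The package offers two M-step schedules with identical fixed points.
`schedule = "ecm"` (default) first maximizes the expected complete-data
log-likelihood jointly over $(\boldsymbol\mu, \mathbf{W})$ — a closed form
obtained by augmenting the latent vector with a constant coordinate — and
then maximizes over $\boldsymbol\Psi$ at the fresh values. Because each step
is an exact conditional maximization of the same surrogate, the observed-data
log-likelihood is provably non-decreasing wherever the E-step is exact.
`schedule = "literal"` computes all three updates simultaneously from the
previous iteration's values, matching the update formulas as usually printed;
this Jacobi-style sweep is not a coordinate ascent and carries no
monotonicity guarantee, though in practice the two schedules behave almost
identically.

Two caveats about monotonicity are worth stating precisely, because the test
suite asserts around them:

1. When a *partially* observed modality block has non-diagonal
   $\boldsymbol\Psi_r$, the conditional expectation of a missing entry used
   here (and in the estimator this package implements),
   $\mathbf{W}_{i\cdot}\mathrm{E}(\mathbf{z}_k \mid \tilde{\mathbf{x}}_k) + \mu_i$,
   omits the term
   $\Psi_{mo}\tilde\Psi_{oo}^{-1}(\tilde{\mathbf x}_k - \tilde{\boldsymbol\mu}
   - \tilde{\mathbf W}\mathrm{E}(\mathbf z_k))$ that the exact conditional
   Gaussian would add. The iteration is therefore an approximate EM in that
   regime and the likelihood can decrease on the order of $10^{-5}$
   relative. With complete data, or in diagonal covariance mode, the E-step
   is exact and the trace is monotone to numerical precision.
2. The ridge update below is an estimator substitution, not the maximizer of
   a penalized surrogate; no fixed objective is monotone under it (we
   verified this by numerical counterexample during development). The
   monitored objective reported in `$objective` is the observed-data
   log-likelihood minus the penalty $\tfrac{n(1-\lambda)}{2}\,
   \mathrm{tr}(\mathbf{R}^{-1})$; it is used for *termination*, not as a
   certified ascent quantity.

Convergence is declared after two consecutive relative changes of the
monitored objective below `tol` (default $10^{-6}$); the two-step rule
prevents a single near-stationary step early in the run from terminating the
iteration. Non-convergence within `max_iter` (default 500) is a warning, not
an error.

## Ridge regularization

With $m$ in the hundreds and $n$ comparable, the blockwise covariance MLE is
noisy. Writing $\boldsymbol\Psi = \boldsymbol\Psi_d^{1/2}\mathbf{R}
\boldsymbol\Psi_d^{1/2}$, the error correlation matrix is shrunk towards the
identity at every M-step,

$$
\hat{\mathbf{R}}_{\text{ridge}} = \lambda\hat{\mathbf{R}} + (1-\lambda)\mathbf{I},
\qquad
\hat{\boldsymbol\Psi}_{\text{ridge}} = \hat{\boldsymbol\Psi} +
\left(\tfrac{1}{\lambda} - 1\right)\hat{\boldsymbol\Psi}_d,
$$

with $\lambda \in (0, 1]$; $\lambda = 1$ is the unpenalized MLE. Note the
covariance form inflates the error variances by $1/\lambda$ — the two
displayed forms are consistent (the correlation matrix of
$\hat{\boldsymbol\Psi}_{\text{ridge}}$ is exactly
$\hat{\mathbf{R}}_{\text{ridge}}$), and the covariance form is what the
M-step applies, from the first iteration onward, which also keeps every block
positive definite throughout (diagonals are additionally floored at
`var_floor = 1e-6`, a negligible bias at data scale). In diagonal mode the
block is truncated to its diagonal before the ridge step. $\lambda = 1/2$ and
$\lambda = 2/3$ are robust defaults; smaller $\lambda$ suits stronger or
noisier residual correlation.

## Choosing the number of latent factors

`gpcca_select_d()` implements consensus-based selection. For every candidate
$d$ the model is fitted from $B$ random initializations (default 10; the
acceptance protocol uses 5), each embedding is clustered, and the $n \times
n$ consensus matrix $\mathbf{C}$ of pairwise co-clustering fractions is
scored by

$$
\mathcal{H} = \sum_{i<j}\mathbf{C}_{ij}\log_2\mathbf{C}_{ij} \le 0,
$$

with $0\log_2 0 = 0$; $\mathcal{H} = 0$ exactly when all $B$ partitions
agree on every pair. The candidate with the largest score wins; ties break
towards the smaller $d$ (parsimony — the paper-style protocol does not
address ties). Within the winning candidate, the initialization whose binary
connectivity matrix is closest to the consensus in RMSE over the
$\binom{n}{2}$ pairs (diagonal excluded) provides the final model and labels.
Failed fits are dropped with a warning (reducing $B$ for that candidate);
only an all-failed candidate is an error.

Clustering uses Louvain modularity optimization at resolution 0.8 on a
shared-nearest-neighbor graph (Euclidean 15-nearest neighbors in the
embedding, Jaccard edge weights over neighbor sets including the point
itself, edges below 1/15 pruned — the construction popularized by the
single-cell toolkits). The resolution is the one tunable the reference
protocol fixes; the neighbor count is configurable and is clamped with a
warning when fewer samples are available. Both the fit seeds and the
clustering seeds derive deterministically from one master seed, so a full
selection run is bit-reproducible.

## The synthetic-data generator

`simulate_multimodal()` reproduces the validation designs used throughout the
package's tests: six clusters of 100 samples, three modalities of 60/120/180
features, a 1:4 informative:noisy feature ratio (12/24/36 informative), and
within-modality AR(1) correlation $\rho^{|i-j|}$ among informative features
scaled by standard deviations drawn from $4\,\mathrm{Beta}(1,1)$. Each
modality splits the six clusters into two groups of three, drawing
informative features from component $u$ or $v$ per a fixed design table; no
single modality separates all six clusters, so integration is genuinely
required. Component mean entries are drawn uniformly from $[1, 2]$ ($u$) and
$[-2, -1]$ ($v$). The $u$-range is an assumption: the source protocol prints
only the $v$-range, and the symmetric counterpart is adopted as the natural
reading. Noisy features are standard normal, independent of cluster.

* **Case A** applies MCAR masking at a chosen rate (masks that would empty a
  sample's column are redrawn).
* **Case B** replaces every normal draw with multivariate $t_3$ (same
  location, same scatter matrix; sampled as scatter-Cholesky times normal
  over $\sqrt{\chi^2_3/3}$) and the noise with univariate $t_3$ — a
  heavy-tailed violation of the Gaussian assumption.
* **Case C** generates complete Gaussian data, then drops whole modalities
  based on a hidden $H_k \sim \mathcal{N}(0,1)$: a subject loses one
  uniformly chosen modality with probability $p$ if $H_k \ge 0$ and $2p$
  otherwise — missingness that depends on an unobservable, i.e. MNAR. The
  at-most-one-modality reading is deliberate: the same mechanism is used
  elsewhere with $p = 0.5$, where independent per-modality drops at
  probability $2p$ would remove every modality of every $H_k < 0$ subject.
  $H_k$ is stored for diagnostics but never exposed to fitting.
* **Case D** swaps one sixth of the within-modality correlation entries
  (among informative features, strictly-lower-triangle positions sampled
  without replacement) with zero-valued cross-modality positions,
  symmetrically, violating the block-diagonal assumption; if the result is
  not positive definite the smallest power-of-ten diagonal jitter restoring
  a minimum eigenvalue of $10^{-6}$ is added.

What the generator does *not* emulate about real multi-omics data: feature
scales spanning orders of magnitude, count/zero-inflated distributions,
batch structure, and informative missingness tied to the data values
themselves. Passing the simulation benchmarks therefore demonstrates correct
estimation and robustness to the stated violations, not end-to-end
performance on raw omics matrices (which should be preprocessed and
transformed before fitting, as usual).

## Evaluation metrics

`adjusted_rand_index()` is the permutation-model chance-corrected Rand index
computed from the contingency table ($1$ iff the partitions coincide).
`normalized_mutual_info()` divides mutual information by, per default, the
arithmetic mean of the two partition entropies (min, geometric-mean and max
normalizations are available); two single-cluster partitions score 1 by the
identical-partition convention. Both are cross-checked in the test suite
against independent implementations (`mclust`, `igraph`).

## Reference protocol sizes

The packaged acceptance script (`scripts/acceptance.R`) and the end-to-end
tests run the Case A and Case C designs at the full generator scale
($n = 600$, $m = 360$, $\rho = 0.7$; Case A with 20% MCAR and
$\lambda = 2/3$, Case C with $p = 0.1$ and $\lambda = 1/2$) with consensus
selection over $d \in \{4, 6, 8\}$, $B = 5$ initializations, selection fits
capped at 150 EM iterations at `tol` $10^{-5}$, and results averaged over 5
replicate seeds. These caps are the package's reference protocol for a
single-CPU run; a full analysis would typically use the default `max_iter =
500`, `tol` $10^{-6}$, $B = 10$ and a wider candidate grid.

## Known limitations

* The missing-data E-step is approximate when a partially observed,
  correlated block occurs (see above); diagonal mode or complete data are
  exact. Imputation inherits the same approximation.
* The ridge iteration has no certified monotone objective; termination is
  based on stabilization of the monitored objective rather than ascent.
* The likelihood is invariant to orthogonal rotation of the factors;
  loadings are identified only up to rotation, and embeddings up to the same
  rotation (distance-based downstream steps are unaffected).
* MNAR mechanisms are handled robustly in the empirical sense demonstrated
  by Case C, but the estimator itself assumes MAR.
* No survival analysis, external integration methods, or visualization are
  included; embeddings and imputed matrices are written as plain TSV for
  downstream tools.
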