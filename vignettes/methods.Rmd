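---
title: "Canonical-correlation integration of multimodal single-cell data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical-correlation integration of multimodal single-cell data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind jointCCA, the design
decisions that were genuinely open, the numerical conventions that make
results reproducible, and what the bundled simulator does and does not
emulate. It is the place to look when a default seems arbitrary: every
choice below states its rationale.

## The integration model

The input is a set of cell-by-feature matrices $X^{(i)} \in
\mathbb{R}^{n\times s(i)}$ for $m$ modalities measured on the same $n$
cells, with no correspondence assumed between features of different
modalities. Each modality is reduced independently to $Y^{(i)} \in
\mathbb{R}^{n \times p(i)}$ (PCA for RNA and protein, LSI for ATAC; any
externally computed embedding, e.g. batch-corrected, can be substituted).
Working in the reduced space makes the cost of everything downstream
$O(p^2 n)$ rather than $O(s^2 n)$ and lets users plug in batch-corrected
embeddings directly.

For two modalities, canonical correlation analysis finds weight vectors
$w_i^{(1)}, w_i^{(2)}$ maximizing the correlation of the variate pair $z_i^{(1)} =
Y^{(1)} w_i^{(1)}$, $z_i^{(2)} = Y^{(2)} w_i^{(2)}$, each new pair
uncorrelated with all earlier ones, for $\hat k = \min(p^{(1)}, p^{(2)})$
pairs in total. The shared space is the sum $Z = Z^{(1)} + Z^{(2)}$ of the
variate matrices, truncated to the $k$ leading components judged
significant (next section). With more than two modalities the same
two-block step is applied sequentially — widest embedding first, then each
next modality against the current shared space, truncating inside the loop.
The sequential heuristic avoids the combinatorial cost of a true
multi-block CCA; its price is that the result depends on the modality
order, which is why the default order (non-increasing dimensionality, ties
by input order) is deterministic and recorded in the output.

Assumptions worth keeping in mind: the shared signal is assumed linear in
the reduced coordinates; all cells must be present in every modality; and
CCA treats the two blocks symmetrically, so a modality that is pure noise
dilutes nothing (its components are filtered) but also contributes nothing.

### Solver

The weights solve the generalized eigenproblem
$$\Sigma_{12}\,\Sigma_{22}^{-1}\,\Sigma_{21}\, w \;=\; \rho^2\, \Sigma_{11}\, w$$
on column-centered data. The implementation whitens with the Cholesky
factor of $\Sigma_{11}$ and solves an ordinary symmetric eigenproblem,
which is numerically stable and returns real, ordered eigenvalues. The test
suite checks this path against two independent implementations — an
explicit whitening-SVD oracle ($\mathrm{svd}(\Sigma_{11}^{-1/2}\Sigma_{12}
\Sigma_{22}^{-1/2})$ built from symmetric eigendecompositions) and base R's
QR-based `cancor` — to $10^{-7}$ over random instances.

Numerical conventions, all of which exist to make outputs bitwise
reproducible and well scaled rather than to change the estimator:

* **Centering.** Columns of $Y^{(1)}, Y^{(2)}$ are mean-centered before
  covariances are formed. A pure cosine-similarity formulation would skip
  centering; PCA/LSI scores are already near-centered, and centering gives
  the standard CCA estimator.
* **Ridge.** $10^{-8}\cdot\mathrm{mean(diag)}$ is added to each
  within-block covariance. This is plumbing against near-singular blocks,
  orders of magnitude below statistical noise.
* **Variate scale.** Each canonical variate is normalized to unit variance,
  so the sum $Z^{(1)}+Z^{(2)}$ weights the two modalities equally; the
  summed component then has variance $2+2\rho_i$, which mildly emphasizes
  well-correlated components.
* **Signs.** Each pair is flipped so that the pair correlates positively
  and the largest-magnitude entry of $w^{(1)}$ is positive; PCA/LSI
  components follow the same largest-loading-positive rule. Eigenvalue ties
  are broken by a stable sort.

### Which components are real? The retention filter

Per component the Pearson correlation $r_i$ of $(z_i^{(1)}, z_i^{(2)})$ is
computed together with the correlation t-statistic $t_i = r_i
\sqrt{(n-2)/(1-r_i^2)}$ and its two-sided p-value, BH-adjusted across the
$\hat k$ components; because canonical correlations are non-increasing, the
retained set is the longest prefix with adjusted $p < \alpha$ (default
$\alpha = 0.05$), matching the contiguous truncation the sequential
algorithm performs.

The bivariate t-test, however, ignores that each $r_i$ is *maximized* over
weight vectors: under complete independence of the two blocks the leading
sample canonical correlation concentrates around $\sqrt{p^{(1)}/n} +
\sqrt{p^{(2)}/n}$ — about $0.14$ at $n = 2000$, $p = 10$ — which the t-test
declares overwhelmingly significant. Measured directly, the t-test rule
retains a median of 6 of 10 components on data with *no* shared structure.
A filter that cannot fail under the null cannot be said to estimate the
latent dimension, so retention defaults to the classical Bartlett–Lawley
sequential test for the number of nonzero canonical correlations,
$$ \chi^2_i \;=\; -\Big(n - 1 - \tfrac{p^{(1)}+p^{(2)}+1}{2}\Big)
   \sum_{j\ge i}\log(1-r_j^2), \qquad
   \mathrm{df}_i = (p^{(1)}-i+1)(p^{(2)}-i+1), $$
BH-adjusted and prefix-truncated exactly as above. Both sets of p-values
are always reported (`p`, `p_adj` for the t-test; `p_dim`, `p_dim_adj` for
the dimension-aware test), and `method = "ttest"` restores the literal
t-test rule for comparison with the original recipe. The acceptance suite
verifies the default filter's calibration: median retained $k \le 2$ on
null data, planted rank 2 recovered in $\ge 90\%$ of replicates, full
retention when the modalities are identical.

## Preprocessing recipes

The recipes reproduce the community-standard pipelines, with constants that
those pipelines leave implicit stated explicitly here:

| step | default | why |
|---|---|---|
| RNA log-normalization | scale factor 10 000 | convention of the standard scRNA-seq pipeline; counts per cell divided by cell total, scaled, `log1p` |
| variable genes | top 3000, variance-stabilizing criterion (loess trend of $\log_{10}$ variance vs $\log_{10}$ mean, z-scores clipped at $\sqrt n$) | the criterion behind the standard pipeline's default gene selection |
| scaling clip | $+10$ after unit-variance scaling | caps single-cell outliers before PCA |
| PCA dims | 50 (RNA), 30 (protein) | the dimensionalities used by the standard bi-/tri-modal workflows |
| protein normalization | CLR per feature across cells: $\log(1+x)$ minus the feature's mean $\log(1+x)$ | antibody counts have strong per-feature background; the across-cell margin preserves relative per-cell signal |
| ATAC TF-IDF | $\log(1 + 10^4\cdot \mathrm{TF}\cdot\mathrm{IDF})$, IDF $= n/\#\{\text{cells with peak}\}$, peaks kept if detected in $\ge 1$ cell | the common ATAC dialect among the several published TF-IDF variants |
| LSI dims | 50, first discarded | the first singular vector of TF-IDF data tracks per-cell depth, verified in the tests on depth-confounded simulations |

Constant features are kept as zero columns (with a warning) rather than
dropped so feature bookkeeping stays aligned with the input. Sparse
matrices stay sparse through TF-IDF; densification happens only at the
reduced $n \times p$ scale. Truncated SVDs use exact LAPACK for small
problems and implicitly restarted Lanczos (irlba) with a fixed internal
seed for large ones, so embeddings are reproducible run to run. Protein
PCA uses all proteins (panels are small; there is no analogue of gene
selection for a 25–200-plex panel).

## Feature interpretation

Features are linked to components by $U = X^\top Z$ with the columns of
$Z$ standardized to unit variance so scores are comparable across
components. $X$ enters as the *normalized* matrix (log-normalized RNA/CLR
protein, TF-IDF ATAC), not raw counts — otherwise sequencing depth would
dominate the scores — and not the scaled matrix, whose clipping distorts
effect sizes. Rankings per component (`top_features`) break ties by feature
id so exports are deterministic even for degenerate score columns.

## Benchmarking metrics

* **Structure score**: Pearson correlation between pairwise Euclidean cell
  distances in $Z$ and in one modality's $Y^{(i)}$, averaged over
  modalities. Above $n(n-1)/2 = 10^5$ pairs, pairs are subsampled uniformly
  without replacement under the caller's seed; exhaustive mode is exact and
  deterministic. Pair subsampling (rather than cell subsampling) keeps the
  estimator unbiased for the full pair population.
* **Silhouette**: mean Euclidean silhouette width of reference labels on
  $Z$.
* **Louvain/ARI sweep**: 20-nearest-neighbor graph on $Z$ (Euclidean,
  unweighted, symmetrized), Louvain at resolutions $0.1, 0.2, \dots, 2.0$
  under a fixed seed, adjusted Rand index against reference labels per
  resolution.
* **Ranking**: per-metric ranks (1 = worst, ties averaged) summed across
  metrics.

All three metrics are verified against brute-force/closed-form oracles on
small fixtures to $10^{-10}$.

## The simulator: what it emulates, and what it does not

`generate_multimodal()` draws a shared latent space and expresses it in
every modality through modality-specific linear loadings:

* $K$ population centers form a **regular simplex** with pairwise distance
  `pop_separation` (default 5.5) in a randomly oriented $(K-1)$-dimensional
  subspace of the `latent_dim`-dimensional (default 10) latent space; cells
  get isotropic Gaussian jitter (`noise_sd`, default 1) around their
  center. The simplex makes every population pair equally separated, so
  simulation difficulty does not fluctuate with the seed. The separation
  of 5.5 jitter units puts populations in the cleanly-separable-but-
  overlapping-tails regime typical of annotated PBMC-style data; the jitter
  spread being comparable to per-dimension center separation reflects real
  within-cell-type heterogeneity (cell states, cycling), which is why the
  latent distance structure is not concentrated in two directions.
* **RNA/protein counts** are negative binomial with dispersion 0.5 and
  per-gene log-rates $0.2$-sd linear in the factors (about one natural-log
  unit of per-gene variation — a realistic fold-change range), lognormal
  per-cell depth factors (sd 0.3).
* **ATAC counts** are Bernoulli detections through a logistic link
  (intercept $-3.5$, giving $\ge 90\%$ sparsity) with depth as a logit
  offset, thickened by a small Poisson term so nonzero counts are mostly
  1–2, mimicking near-binary accessibility data.

`generate_null_multimodal()` keeps the count families but gives each
modality its own independent factors — the null for filter calibration.
`simulate_shared_embeddings()` plants exact canonical correlations at the
embedding level, giving ground truth where "shared rank" is well defined.

What the simulator does **not** emulate: doublets and empty droplets,
batch effects, gene–peak regulatory coupling, mean–variance trends beyond
the NB family, trajectory (continuous) population structure, and the
heavy-tailed feature-count distributions of real panels. Passing tests on
this simulator therefore demonstrate correctness of the estimator and
calibration of the filter under the stated generative model — not
robustness to every artifact of real data. One consequence of the
nonlinear count link is worth knowing: with strong loadings, PCA/LSI of
counts carries low-order harmonics of the latent factors, which are
genuinely shared across modalities, so the retained $k$ can slightly
exceed the linear latent rank. That is the filter being right about the
data, not a miscalibration.

## Problem sizes and runtime

The test and acceptance workloads are sized for a laptop-class single
core: 2000-cell bi-modal fixtures for end-to-end runs, 100 replicates at
$n = 2000, p = 10$ for null calibration, 50 random instances for solver
oracle checks. The solver itself is $O(\max(p)^2 n)$ for covariances plus
an $O(p^3)$ eigendecomposition, so real datasets of $10^4$–$10^5$ cells at
$p \le 50$ remain cheap; the preprocessing SVDs dominate in practice.

## Known limitations

* The sequential multimodal heuristic is order-dependent; the default
  ordering is a convention, not an optimum.
* Cross-modality alignment is linear in the reduced coordinates; strongly
  nonlinear shared structure appears as several linear components.
* The structure score requires a low-dimensional representation and its
  value depends on the variance profile of the compared spaces; a whitened
  shared space cannot exceed the distance correlation attainable given its
  flat per-component variance.
* Batch correction is out of scope: supply corrected embeddings (`method =
  "external"`) when batches are present.
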