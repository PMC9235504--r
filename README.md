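# jointCCA

Multimodal single-cell experiments measure several molecular layers — the
transcriptome, surface proteins, chromatin accessibility — in the *same*
cells. Each modality comes with its own scale, dimensionality and noise, and
the central analysis question is how to combine them into one latent space
that represents every cell jointly, without hand-tuning a latent rank per
dataset.

jointCCA builds that shared space with canonical correlation analysis (CCA)
on per-modality reduced embeddings. It is aimed at analysts working with
CITE-seq, 10x Multiome, SHARE-seq, DOGMA-seq or TEA-seq style data who want
a fast, parameter-free, interpretable integration, and at methodologists who
need the accompanying benchmarking metrics (structure preservation,
silhouette, clustering agreement) and a seeded multimodal simulator.

## Method

Each modality's cell-by-feature matrix `X⁽ⁱ⁾ ∈ R^{n×s(i)}` is first reduced
independently, `Y⁽ⁱ⁾ = f⁽ⁱ⁾(X⁽ⁱ⁾)`:

* **RNA** — log-normalization, 3000 highly variable genes (variance-
  stabilizing criterion), scaling, 50-component PCA;
* **protein/epitope** — centered log-ratio transform per feature across
  cells, 30-component PCA;
* **ATAC** — TF-IDF weighting of peaks, truncated SVD (LSI) keeping 50
  components and discarding the first, which tracks sequencing depth.

For two modalities, CCA finds weight vectors maximizing the correlation of
the paired variates

    z₁⁽¹⁾ = Y⁽¹⁾ w₁⁽¹⁾,   z₁⁽²⁾ = Y⁽²⁾ w₁⁽²⁾,
    (w₁⁽¹⁾, w₁⁽²⁾) = argmax cos(z₁⁽¹⁾, z₁⁽²⁾),

repeated `k̂ = min(p⁽¹⁾, p⁽²⁾)` times with successive variates uncorrelated
with all previous ones. The solver reduces the problem to the generalized
eigenproblem `Σ₁₂ Σ₂₂⁻¹ Σ₂₁ w = ρ² Σ₁₁ w` on column-centered data. The
shared representation is the sum of the unit-variance variate matrices,
`Z = Z⁽¹⁾ + Z⁽²⁾`, truncated to the prefix of components whose
cross-modality correlation is significant after Benjamini–Hochberg
correction (a dimension-aware Bartlett–Lawley test by default; the plain
correlation t-test is available as an option — see the methods vignette).
Additional modalities are folded in sequentially, widest embedding first:
`Z ← truncate(Z + Y⁽ⁱ⁾W⁽²⁾)` at each step.

Components are interpreted by scoring original features against the latent
space, `U = Xᵀ Z` (columns of `Z` standardized), giving ranked gene/peak/
protein lists per canonical component.

## Worked example

```r
library(jointCCA)

ds <- generate_multimodal(n_cells = 1000, seed = 7,
                          modality_specs = list(
                            rna  = list(n_features = 800,  family = "nb"),
                            atac = list(n_features = 1500, family = "bp")))
rna  <- preprocess_modality(ds$modalities$rna,  n_dims = 30)
atac <- preprocess_modality(ds$modalities$atac, n_dims = 30)

latent <- integrate_multi(list(rna = rna, atac = atac))
latent
#> <integrated_latent> 1000 cells x 10 components (rna + atac)

head(latent$component_tests[, c("component", "r", "p_adj", "p_dim_adj", "retained")], 3)
#>   component         r         p_adj p_dim_adj retained
#> 1         1 0.9321885  0.000000e+00         0     TRUE
#> 2         2 0.9269589  0.000000e+00         0     TRUE
#> 3         3 0.7698468 7.366305e-196         0     TRUE

report <- benchmark_report(latent, list(rna = rna, atac = atac), ds$labels, seed = 7)
report
#> <benchmark_report> structure mean 0.660 | silhouette 0.126 | best ARI 0.970

norm <- lognormalize_rna(ds$modalities$rna)
top_features(feature_scores(norm, latent), component = 1, n_top = 5)
#>      feature_id    score
#> 1 rna_feat00506 1205.816
#> 2 rna_feat00523 1151.080
#> ...
```

Ten canonical components are retained (the simulated latent rank is 10);
the first components correlate strongly across modalities (`r ≈ 0.93`), the
Louvain sweep recovers the three simulated populations at ARI 0.97, and the
mean structure score of 0.66 says pairwise cell distances in the shared
space track both modalities' own embeddings. The feature scores rank the
genes most associated with the first canonical component.

A command-line wrapper with `simulate`, `preprocess`, `integrate`,
`benchmark` and `run` subcommands is installed at
`system.file("cli", "jointcca", package = "jointCCA")`.

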