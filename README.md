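# gpcca

Generalized probabilistic canonical correlation analysis for integrating two
or more data modalities — e.g. DNA methylation, mRNA and miRNA expression
measured on the same samples — with full or partial observations.

## The problem and the model

Multi-modal datasets are routinely incomplete: single entries are missing,
and often whole modalities are absent for some subjects (a sample was never
assayed on one platform). Most integration methods either require complete
data or bolt on an imputation step. `gpcca` instead treats the stacked data
`X` (features `m = Σ m_r` by samples `n`) as a latent factor model

    x_k = W z_k + μ + ε_k,   z_k ~ N_d(0, I),   ε_k ~ N_m(0, Ψ),

where the loading matrix `W` ties all modalities to a shared `d`-dimensional
latent space and the error covariance `Ψ` is **block diagonal**: residual
correlations are allowed within a modality, forbidden across modalities. All
cross-modality structure must flow through the factors, which makes the
posterior means `E(z_k | observed part of x_k)` a denoised, integrated
embedding for clustering — and which distinguishes the model from
probabilistic PCA (diagonal errors) on one side and an unidentifiable full
covariance on the other.

Estimation is by an EM algorithm that works directly on the observed entries
of each subject (per-subject Woodbury algebra, blockwise inversions, cached
factorizations), so entry-wise and modality-wise missingness need no prior
imputation; missing values fall out of the E-step as `W_i E(z_k|·) + μ_i`.
The error correlation matrix is ridge-shrunk towards the identity at every
M-step, `R ← λR + (1−λ)I` with `λ ∈ (0,1]`, stabilizing the blockwise
covariance estimates in high dimensions. The number of latent factors is
selected by consensus: fit `B` random initializations per candidate `d`,
Louvain-cluster each embedding on a shared-nearest-neighbor graph, and keep
the candidate whose `B` partitions co-cluster most consistently (consensus
score `Σ_{i<j} C_ij log2 C_ij ≤ 0`, equal to 0 iff all runs agree), then the
initialization closest to the consensus in connectivity RMSE.

The package also ships the four-case synthetic benchmark generator used in
its tests (Gaussian/heavy-tailed data, MCAR and modality-wise MNAR
missingness, cross-modality correlation violations), ARI/NMI partition
metrics, TSV readers/writers and a small CLI.

## Worked example

```r
library(gpcca)

# simulate the benchmark design: 6 clusters x 100 samples, modalities of
# 60/120/180 features, AR(1) rho = 0.7, 20% of entries missing at random
sim <- simulate_multimodal("A", rho = 0.7, missing_rate = 0.2, seed = 1)
#> gpcca_sim: case A | rho = 0.7 | 600 samples in 6 clusters
#> multimodal_dataset: 3 modalities, 360 features, 600 samples
#>   modality1: 60 features, 80.0% observed
#>   modality2: 120 features, 80.0% observed
#>   modality3: 180 features, 79.9% observed

# fit with 6 latent factors and ridge weight 2/3
fit <- gpcca_fit(sim$data, d = 6, lambda = 2/3, max_iter = 200, seed = 2)
#> gpcca fit: d = 6 , lambda = 0.6666667 , iterations = 116 (converged)
#>   final log-likelihood: -268199.6

# cluster the latent embedding and compare with the true labels
cl <- cluster_embedding(fit$embedding, resolution = 0.8, seed = 2)
adjusted_rand_index(cl, sim$labels)   # 0.756
normalized_mutual_info(cl, sim$labels) # 0.864

# impute the missing entries; observed values are returned untouched
completed <- gpcca_impute(fit, sim$data)
```

On this replicate the fitted embedding recovers the cluster structure far
above what PCA on the raw concatenated matrix achieves (ARI ≈ 0.5 on the
same data), and model-based imputation reaches RMSE 1.31 against the held-out
truth versus 1.54 for per-feature mean imputation. Consensus selection
(`gpcca_select_d(sim$data, c(4, 6, 8), B = 5, lambda = 2/3, seed = 1)`)
automates the choice of `d` and of the best initialization; averaged over
replicate seeds the selected models reproduce the benchmark clustering
accuracies (see below).

The same pipeline is available from a shell via the thin wrapper in
`inst/cli/gpcca.R`:

```sh
Rscript inst/cli/gpcca.R simulate --case A --rho 0.7 --missing-rate 0.2 --seed 1 --out-dir sim
Rscript inst/cli/gpcca.R select-d --data sim/modality1.tsv,sim/modality2.tsv,sim/modality3.tsv \
    --candidates 4,6,8 --B 5 --lambda 0.667 --seed 1 --out-dir run
Rscript inst/cli/gpcca.R evaluate --labels run/clusters.tsv --ref sim/labels.tsv
```

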