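# sceodesic

Cell-state-specific gene coexpression for single-cell RNA-seq, estimated on
the Riemannian manifold of symmetric positive-definite (SPD) matrices.

## The problem

Gene *programs* — sets of covarying genes — characterize cell states better
than individual transcripts, but global factorizations (PCA, NMF) estimate
one covariance structure for a whole experiment and miss state-specific
covariation. Estimating covariance *locally*, per cell state, raises a
geometric problem: coexpression matrices are SPD and live on a curved cone,
so entrywise (Euclidean) differences between them are not meaningful.

This package compares coexpression on the tangent space of the SPD manifold
using the **log-Euclidean metric**

```
d_logΣ(Σ₁, Σ₂) = ‖ log Σ₁ − log Σ₂ ‖_F ,
```

a true metric computable from one eigendecomposition per matrix
(`log Σ = Q diag(log λ) Qᵀ`) that lower-bounds the affine-invariant geodesic
distance. Around this metric it implements the full local-to-global
pipeline:

1. **Cohorts** — partition cells into transcriptionally coherent cohorts
   (diagonal-covariance Gaussian mixture, k-means, or supplied labels) on
   log-normalized expression restricted to `h` highly variable genes.
2. **Condition-volume normalization** — regularize each cohort's sample
   covariance `Σᵢ = Uᵢ Dᵢ Uᵢᵀ` by flooring eigenvalues at `σ_max/M` (the
   Frobenius-nearest spectrum with condition number ≤ M) and rescaling so
   the spectrum lies in `[1, M]`; after the matrix log the floored
   directions are exactly zero and `det ≤ M^h`.
3. **Programs (PVD)** — pool each cohort's leading eigenvectors (up to 90%
   cohort variance) and run (sparse) PCA on the pool, treating each
   eigenvector as an observation in gene space; the unit-norm components
   `Û` are the study-wide gene programs.
4. **Reconstruction** — re-express each cohort in the shared programs by
   minimizing `‖log Σ̃ᵢ − log(Û Sᵢ Ûᵀ)‖_F` over diagonal `Sᵢ`, solved in
   closed form by `[Ŝᵢ]ⱼⱼ = [Ûᵀ log Σ̃ᵢ Û]ⱼⱼ`; every cell inherits its
   cohort's loading vector (the `X_sceodesic` embedding).

It also ships the benchmark machinery used to validate the metric: a
chemical-Langevin gene-regulatory-network simulator producing two cell
types with matched means but differently wired master regulators (plus
dropout/outlier technical noise), case–control scores, distance-threshold
AUROC, Spearman time correlations, and Hedges' *g*.

Intended users: computational biologists analyzing scRNA-seq who want
interpretable, locally informed gene programs, and methods developers who
need a principled metric between coexpression matrices.

## Worked example

Simulate two cell types with identical mean expression but disjoint
coexpression blocks, fit the pipeline, and score how well each metric
separates the types:

```r
library(sceodesic)

grn <- build_two_type_grn(n_genes = 60, n_blocks = 3, block_size = 8, hill_k = 2)
Xa <- simulate_expression(grn$type_a, 600, seed = 1)
Xb <- simulate_expression(grn$type_b, 600, seed = 2)
rownames(Xa) <- paste0("a_", 1:600); rownames(Xb) <- paste0("b_", 1:600)
X <- rbind(Xa, Xb)

fit <- sceodesic(X, h = 40, n_cohorts = 4, method = "gmm", seed = 7)
fit
#> <sceodesic_fit> 1200 cells, 40 genes/programs, 4 cohorts (gmm)
#>   M = 50, lambda = 0, v_pvd = 0.9; reconstruction residuals 4.16-4.64

head(tidy(fit))
#> # A tibble: 6 × 5
#>   cohort program   loading residual n_cells
#>    <int> <chr>       <dbl>    <dbl>   <int>
#> 1      1 program_1  2.03       4.52     373
#> 2      1 program_2  2.10       4.52     373
#> 3      1 program_3  1.80       4.52     373
#> 4      1 program_4  1.75       4.52     373
#> 5      1 program_5  0.0762     4.52     373
#> 6      1 program_6  0.221      4.52     373
```

The `loading` column is the activity of each study-wide program in a
cohort, on the log (tangent-space) scale: ~2 means that program's variance
direction is inflated by a factor `e² ≈ 7` relative to the floored
spectrum; values near 0 mean the program is inactive in that cohort.
`residual` is the log-Euclidean reconstruction error of the cohort's
covariance in the shared dictionary.

```r
Xn <- normalize_counts(X)[, fit$hvg$selected_indices]
case_control_score(Xn[1:600, ], Xn[601:1200, ], metric = "logcov",
                   n_partitions = 100, seed = 3)
#> # A tibble: 1 × 7
#>   metric inter intra score intra_se n_partitions  seed
#>   <chr>  <dbl> <dbl> <dbl>    <dbl>        <int> <int>
#> 1 logcov  8.07 0.861  9.38   0.0154          100     3
```

The score is the inter-type distance divided by the within-control sampling
noise; under the same settings the mean-expression metric scores 3.05 and
the Euclidean covariance metric 5.76 — the log-Euclidean metric separates
the two types best even though their mean expression is matched by
construction.

A thin command-line driver over these functions (subcommands `simulate`,
`fit`, `evaluate`, `distance`) is installed at `inst/cli/sceodesic.R`.

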