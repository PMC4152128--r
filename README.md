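# cipmd

Supervised sparse gene selection from labeled expression matrices by a
class-information-based penalized matrix decomposition (CIPMD).

## The problem

Genome-scale expression experiments measure thousands of genes in a handful
of samples, but the genes that actually respond to a condition — the *core
genes* of, say, an abiotic stress response in plants — are a small fraction
of the total. Sparse matrix-decomposition methods (sparse PCA, penalized
matrix decomposition) find them by forcing most gene loadings to exactly
zero, but the classical versions are unsupervised: they ignore the sample
class labels (control vs. stress, stress severity levels) that the
experiment provides. CIPMD injects that class information before the sparse
decomposition, which improves how reliably the responding genes are ranked
at the top.

## The method

Given a genes × samples matrix **X** (p × n, rows centered) with C labeled
classes of sizes n_i, class means m_i and grand mean m:

1. **Scatter matrices.** The between-class scatter
   S_b = Σᵢ nᵢ (mᵢ − m)(mᵢ − m)ᵀ and within-class scatter
   S_w = Σᵢ Σⱼ (x_ij − mᵢ)(x_ij − mᵢ)ᵀ are combined into the total
   scatter S_t = S_b − β S_w, with β = tr(S_b)/tr(S_w) by default, so that
   directions separating the classes are rewarded and directions of
   within-class spread penalized. S_b and S_w are held in low-rank factored
   form (p × C and p × n); no p × p matrix is ever allocated.
2. **Embedding.** S_t has rank ≤ C + n. Its SVD S_t = U Λ Uᵀ (singular
   values = |eigenvalues|, computed through a thin QR and a small dense
   eigensolve) gives the class-informed data matrix **D** = U Λ^α. The
   power α > 0 (default 2) amplifies the dominance of the leading
   class-discriminative directions.
3. **Sparse decomposition.** D is decomposed by a rank-one penalized matrix
   decomposition: maximize uᵀDv subject to ‖u‖₂ = 1, ‖v‖₂ = 1 and
   ‖u‖₁ ≤ c, with c = γ√p, γ ∈ (0, 1]. The alternating solution
   soft-thresholds Dv (threshold found by binary search on the L1
   constraint) and renormalizes Dᵀu. Further factors come from deflating
   the residual. The sparse left factor u is the *eigensample*.
4. **Selection.** Genes with nonzero eigensample entries, ranked by |u|
   (maximum over factors when K > 1), are the candidate core genes; the top
   `n_select` (500 by convention) are reported.

Setting `labels = NULL` skips steps 1–2 and runs the penalized
decomposition directly on X: the plain unsupervised PMD baseline.

## Worked example

```r
library(cipmd)

sim <- simulate_expression(p = 2000, n = 16, design = "four-class",
                           support_size = 125, snr = 0.5, seed = 42)
fit <- cipmd(sim$x, sim$labels, gamma = 0.5, alpha = 2, n_select = 500)
fit
#> Class-information-based penalized matrix decomposition
#>   2000 genes x 16 samples; gamma = 0.5 (c = 22.361), K = 1
#>   beta = 0.9124 (tr S_b = 2.728e+04, tr S_w = 2.99e+04), alpha = 2, rank r = 15
#>   eigensample nonzeros: 836; selected genes: 500 (n_select = 500)
#>   top genes: gene90, gene67, gene104, gene57, gene89 ...

identification_accuracy(fit, sim$truth)
#> [1] 0.964
```

The simulated matrix plants 500 relevant genes (4 disjoint blocks of 125,
carried by four dominant sparse eigenvectors) among 2000; `snr = 0.5`
means the noise carries twice the Frobenius power of the signal. The fit
reports the scatter
trade-off β it computed, the rank of the total scatter matrix (15 =
C + n − 1 after centering and the rank-deficiency cutoff), and how many
eigensample entries stayed nonzero at this sparsity (836, of which the 500
largest are returned). The accuracy line says 96.4% of the planted genes
were recovered among the 500 selected. `summary(fit)`, `coef(fit)`,
`plot(fit)` and `residuals(fit)` give the usual views of the fit;
`write_selection(fit, "genes.tsv")` exports the ranked list.

With real data, use `read_expression("expr.tsv")` and
`read_labels("labels.tsv", x)` in place of the simulation. A command-line
wrapper with `select`, `simulate` and `benchmark` subcommands is installed
at `inst/scripts/cipmd.R`.

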