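# imkl — interactive multi-kernel learning for multi-omics subtyping

`imkl` identifies molecular subtypes of patients from multiple omics
layers (e.g. miRNA expression, mRNA expression, DNA methylation) measured
on the same cohort. Most integrative clustering methods combine the
layers additively and can only capture signal that is visible in at
least one layer on its own. `imkl` additionally models **omics–omics
interactions**: subtype structure that emerges only from the joint
pattern across layers.

It is aimed at computational biologists doing unsupervised cancer (or
other disease) subtyping from matched continuous omics matrices, and at
methodologists who want a testbed where interaction-only subtype signal
can be planted and recovered.

## Method

For M omics layers on n patients:

1. **Marginal kernels.** Each layer gives a scaled exponential
   similarity kernel
   `K(i,j) = exp( -rho^2(x_i, x_j) / (mu * eps_ij^2) )`,
   where `rho` is the Euclidean distance and
   `eps_ij = (mean(rho(x_i, N_i)) + mean(rho(x_j, N_j)) + rho(x_i, x_j)) / 3`
   is a pair-adaptive local length scale built from each sample's
   `k_eps` nearest neighbours.
2. **Interaction kernels.** For every layer subset of size 2..M the
   Hadamard (element-wise) product of the marginal kernels, e.g.
   `K^{1x2} = K^1 ⊙ K^2`, `K^{1x2x3} = K^1 ⊙ K^2 ⊙ K^3`. The Schur
   product theorem keeps them valid (PSD, unit-diagonal) kernels; for
   M = 3 the basis has L = 7 members.
3. **Unsupervised weight learning.** A k-nearest-neighbour graph is
   built from every kernel; `W_ij` counts in how many graphs the pair
   (i, j) is an edge. The weights `beta` minimize the topology-
   preservation objective
   `sum_ij W_ij || Delta_i(beta) - Delta_j(beta) ||^2` over the
   probability simplex (`beta_l >= 0`, `sum beta_l = 1`), a quadratic
   program `min beta' S beta` whose cost matrix `S` is assembled from
   profile differences of the (centered, energy-normalized) kernels.
4. **Fusion and clustering.** The meta-kernel
   `K_final = sum_l beta_l K^l` is formed, the number of subtypes is
   chosen by the eigengap of its normalized similarity Laplacian
   (`C* = argmax_{k>1} (lambda_{k+1} - lambda_k)`), and patients are
   partitioned by k-means on the rows of `K_final`.

The package also ships a synthetic multi-omics generator with planted
subtype structure — including an XOR mode in which no single layer
carries the subtype signal — plus cluster-linked survival times,
evaluation metrics (adjusted Rand index, silhouette, Davies–Bouldin,
log-rank), and a patient/feature resampling stability harness.

## Worked example

```r
library(imkl)

spec <- synthetic_spec(n = 150, k_true = 3, seed = 42,
                       survival = list(baseline_hazard = 0.1,
                                       hazard_ratios = c(1, 2, 4),
                                       censoring_rate = 0.2))
sim    <- generate_multiomics(spec)          # 3 layers, 100 features each
layers <- align_and_standardize(sim$datasets)
fit    <- imkl_fit(layers)
fit
#> <imkl_result> n = 150, k = 3 (eigengap)
#> <weight_vector> kernel weights (simplex):
#>     K1     K2     K3   K1x2   K1x3   K2x3 K1x2x3
#> 0.2776 0.3910 0.3314 0.0000 0.0000 0.0000 0.0000

adjusted_rand_index(fit$assignment$labels, sim$truth$labels)
#> [1] 1

lr <- logrank_test(sim$truth$survival_table, fit$assignment$labels)
sprintf("log-rank chisq = %.2f, p = %.3g", lr$statistic, lr$p_value)
#> [1] "log-rank chisq = 56.32, p = 5.9e-13"
```

The eigengap correctly selects three subtypes, the partition matches the
planted truth exactly (ARI = 1), the learned weights spread over the
informative kernels, and the recovered subtypes separate survival
sharply because hazard ratios of 1/2/4 were planted per subtype.

From the shell, the same pipeline runs via the bundled CLI:

```sh
Rscript inst/cli/imkl.R simulate --out simdata --n 150 --k-true 3
Rscript inst/cli/imkl.R run --layers simdata/layer1.tsv,simdata/layer2.tsv,simdata/layer3.tsv --out results
Rscript inst/cli/imkl.R evaluate --clusters results/clusters.tsv --truth simdata/truth.tsv
```

`run` writes `clusters.tsv`, `weights.tsv`, `eigengap.tsv` and
`run.log` to the output directory.

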