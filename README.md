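# hcpnorm

Removing known and hidden confounding covariates from RNA-seq expression
matrices, built around the HCP model — **H**idden **C**ovariates with
**P**rior.

## The problem

Bulk RNA-seq expression measurements carry systematic, confounding
variability: sequencing depth, GC and gene-length biases, batch and lane
effects, and unmeasured ("hidden") technical or biological factors with
broad effects across the transcriptome. Left uncorrected, these produce
spurious correlations among subjects and genes — costing power in cis-eQTL
mapping and planting false edges in co-expression networks. `hcpnorm` is
for analysts who want to residualize a subjects × genes log-expression
matrix against both measured covariates and inferred hidden factors before
downstream association or network analysis.

## The model

Log-scale expression `Y` (n subjects × g genes, genes standardized) is
modeled as covariate effects plus noise, and the normalized signal is the
*residual* after subtracting the estimated effects. The package implements
the members of this residual family:

- **Ridge** (known covariates only): `β̂ = (FᵀF + λI)⁻¹FᵀY`, residual
  `Y − Fβ̂`, with `F` the n × m known-covariate matrix.
- **SVD**: remove the top-k principal components (the best rank-k
  approximation), residual `Y − U_k D_k V_kᵀ`.
- **SVD + tech**: ridge on `F` first, then SVD on the residual; also
  available as a full alternating scheme.
- **HCP**: hidden factors `Z` (n × k) with a Gaussian prior centred on
  linear combinations of the known covariates, fitted by minimizing

  ```
  ‖Y − Z B‖²_F + λ₁‖Z − F U‖²_F + λ₂‖B‖²_F + λ₃‖U‖²_F
  ```

  over `Z`, `B` (k × g loadings) and `U` (m × k covariate-to-factor map),
  by block coordinate descent with closed-form updates (each block problem
  is convex; the objective decreases monotonically). The residual is
  `Y − ZB`. The prior strength λ₁ trades off removing the largest expression
  trends against preferentially removing *patterns that resemble the known
  covariates* — which is what makes HCP robust when the downstream analysis
  (e.g. co-expression) itself depends on broad biological structure.

The package also builds the three standard subject-level technical
covariates (sequencing depth, per-subject GC bias, per-subject length bias),
computes log2 RPKM, and ships the two evaluation pipelines used to compare
normalizations: a cis-eQTL Spearman scan (SNPs within 100 kb of the TSS,
Benjamini–Hochberg FDR) and a co-expression evaluation (Pearson network,
label propagation, cross-validated area under the precision-recall curve).
A seeded synthetic-data generator with planted truth makes the whole
pipeline testable offline.

## Worked example

Simulate a confounded study (60 subjects, 200 genes, a hidden confounder
correlated with three known covariates, cis effects planted on 30% of
genes), fit HCP, and compare cis-eQTL discoveries before and after
normalization:

```r
library(hcpnorm)

sim  <- generate_expression(n = 60, g = 200, m = 3, k = 3, loading_sd = 1,
                            factor_noise_sd = 0.6, seed = 1001)
ann  <- generate_gene_annotation(200, seed = 1002)
geno <- generate_genotypes(60, ann, snps_per_gene = 2, seed = 1003)
planted <- plant_eqtls(sim$expression, geno, ann, fraction_of_genes = 0.3,
                       effect_size = 0.8, seed = 1004)

Y   <- standardize_genes(planted$expression)
fit <- hcp_fit(Y, sim$covariates, k = 10, lambda1 = 30, seed = 1)
fit
#> HCP fit: 60 subjects x 200 genes, k = 10
#>   lambda = (30, 1, 1); 181 iterations, converged; objective 4360.2

variance_explained_by_known(fit, sim$covariates)$overall
#> [1] 0.9608
```

96% of the variance of the removed component `ZB` is explained by the known
covariates — the prior keeps the inferred factors anchored to measured
artifacts. Scanning cis pairs before and after:

```r
pairs <- pair_cis(ann, geno)
count_discoveries(spearman_scan(Y, geno, pairs))
#>   level n_pairs n_genes
#> 1  0.01       2       2
#> 2  0.05       9       9
#> 3  0.10      15      15
count_discoveries(spearman_scan(hcp_residual(Y, fit), geno, pairs))
#>   level n_pairs n_genes
#> 1  0.01      14      14
#> 2  0.05      34      34
#> 3  0.10      54      53
```

Normalization multiplies 10%-FDR discoveries by ~3.6 on this draw (15 →
54), recovering planted cis effects that the confounder masked. `tidy()`,
`glance()` and `autoplot()` summarize fitted models; `hcp_cli()` /
`exec/hcpnorm` expose `simulate`, `covariates`, `normalize`, `eqtl` and
`coexpr` subcommands for shell use.

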