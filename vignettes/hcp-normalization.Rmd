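---
title: "Modeling and removing hidden covariates from RNA-seq expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and removing hidden covariates from RNA-seq expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcpnorm)
```

## The residual framework

All normalizers in this package share one generative picture: observed
log-scale expression $Y$ ($n$ subjects $\times$ $g$ genes) is Gaussian
around a mean that is linear in subject-level covariates, some measured
($F$, $n \times m$) and some not ($Z$, $n \times k$), and the quantity
carried forward to downstream analysis is the residual after subtracting
the estimated covariate effects. Working in log space with a Gaussian
likelihood is a deliberate simplification of count noise: it yields
closed-form estimators throughout, and the main association analysis this
package supports — a Spearman scan — depends only on ranks, which the log
transform preserves.

Three assumptions deserve emphasis. First, covariate effects are additive
on the log scale and linear per gene. Second, hidden covariates are
*subject-level* patterns affecting many genes; gene-level constants (such
as a gene's length acting equally in every subject) vanish when genes are
standardized and are deliberately out of scope. Third, missing values have
no mechanism in the model, so input tables with missing cells are rejected
rather than imputed.

## The HCP model and its solver

HCP departs from plain factor removal through its prior: hidden factors
are drawn around linear combinations of the known covariates,
$Z \sim \mathcal{N}(FU, \cdot)$, giving the objective

$$\|Y - ZB\|_F^2 + \lambda_1\|Z - FU\|_F^2 + \lambda_2\|B\|_F^2
  + \lambda_3\|U\|_F^2.$$

The objective is block-convex, and each block has an exact closed-form
minimizer:

$$U \leftarrow (\lambda_1 F^\top F + \lambda_3 I)^{-1}\lambda_1 F^\top Z,
\quad
Z \leftarrow (YB^\top + \lambda_1 FU)(BB^\top + \lambda_1 I)^{-1},
\quad
B \leftarrow (Z^\top Z + \lambda_2 I)^{-1} Z^\top Y.$$

Note the $\lambda_1$ factors in the $U$ update: they are required for the
update to be the exact minimizer of the objective for general
$\lambda_1$ (they cancel only when $\lambda_1 = 1$), and exact block
minimization is what guarantees the monotone descent that the test suite
asserts on every sweep.

Numerical choices, all deliberate:

- **Update order** is $U \to Z \to B$ per sweep. Any fixed cyclic order is
  valid under block convexity; one order is fixed for reproducibility.
  Without covariates the prior term disappears and the sweep becomes
  $B \to Z \to B$, because $B$ starts at zero and the $Z$ solve needs
  $BB^\top$ nonsingular.
- **Initialization**: $U^0$ is a seeded standard normal scaled by
  $1/\sqrt{m}$ and $Z^0 = FU^0$, i.e. the start lies on the prior
  manifold; $B^0 = 0$. Identical seed and inputs give a bit-identical fit.
- **Convergence** is declared when the relative objective change per sweep
  falls below `tol` (default `1e-6`); `max_iter` defaults to 500 and
  non-convergence is a warning carrying the final relative change, never a
  silent success. A much smaller `tol` (down to `1e-15`) is meaningful:
  near the optimum the objective is locally quadratic, so parameter
  accuracy scales like the square root of the objective accuracy, and the
  fixed-point checks in the tests use tight tolerances for exactly this
  reason.
- **Degenerate inputs**: a singular $BB^\top$ in the covariate-free mode
  is an error suggesting a larger $\lambda_2$ or smaller $k$; NaNs in any
  update abort with the iteration number.

The residual is $Y - ZB$: the known covariates act on the residual only
through the prior on $Z$, not through a separate explicit $F\beta$ term.
This matches the view of the removed component as the hidden-covariate
part; anyone wanting the explicit known-covariate residual can compose
`residual_known()` with the HCP fit.

### Parameters that matter

- `k` (hidden factors): capacity of the removal, default 20 — the setting
  used for eQTL-scale studies of real LCL datasets. At the desk scale of
  the synthetic experiments in this package (60 subjects, 200–250 genes)
  we use `k = 10` throughout, matching the component count at which plain
  PC removal performs best on the eQTL task, so HCP and SVD comparisons
  are capacity-matched.
- `lambda1` (prior strength, unitless): the HCP-defining parameter. Large
  values force $Z$ into the column span of $F$ (the package tests this
  limit at $\lambda_1 = 10^8$); small values approach unconstrained
  factorization. In the synthetic experiments `lambda1 = 30` encodes a
  strong but not binding prior. On real data the intended procedure is
  cross-validation against the downstream task, and the defaults
  `(1, 1, 1)` are starting points, not recommendations.
- `lambda2`, `lambda3`: ridge penalties on $B$ and $U$. Which of the two
  penalty symbols attaches to which matrix is a convention (this package
  follows the released-implementation convention: $\lambda_2$ on $B$,
  $\lambda_3$ on $U$); since both are plain named arguments, the opposite
  convention is obtained by swapping the values.
- Known covariates are standardized by default in
  `assemble_covariates()`, so penalties act on comparable scales.

### Diagnostics

`variance_explained_by_known()` reports how much of the removed component
tracks the measured covariates: each column of $Z$ is regressed on $F$
(per-factor $R^2$), and the overall fraction weights each factor by
$\|B_{j\cdot}\|^2\|Z_j\|^2$ — the squared magnitude the factor contributes
to $ZB$. The $R^2$ itself is scale-invariant in $Z$, so the weights carry
the factor scales; with `nonlinear = TRUE` the regressors gain squares and
pairwise products of covariates, quantifying non-linear covariate effects.

## The other normalizers

`ridge_fit()`/`residual_known()` implement the known-only case;
`svd_remove()` removes the top-$k$ principal components (genes are
standardized first by default, the usual convention so components are not
dominated by mean expression; a sign convention — largest-magnitude
element of each component positive — makes outputs deterministic);
`svd_plus_tech()` composes the two; and `iterate_known_hidden()` alternates
ridge and SVD to a joint optimum, initialized with the hidden part at zero
so its first sweep *is* the two-step composition. All residuals satisfy
exact additive reconstruction, tested to $10^{-10}$.

## Technical covariates and RPKM

Sequencing depth is the per-subject total of mapped reads. GC and length
bias are per-subject Pearson correlations between the subject's per-gene
log counts and per-gene GC fraction (resp. length): a unitless summary of
how much of the subject's expression profile the gene property explains.
Pearson (not Spearman) is used because the quantity of interest is
explained *linear* variation; the correlations are invariant to adding a
per-subject constant to log counts, so they do not simply restate depth.
Log2 RPKM is $\log_2(c + pc) - \log_2(d/10^6) - \log_2(\ell/10^3)$ with
count $c$, depth $d$ and length $\ell$; the default pseudocount is 1
because zero counts survive the expressed-gene filter in small simulated
data, and the pseudocount is exposed wherever logs are taken.

Whether bias correlations are computed on raw-log or RPKM-log values is a
genuinely open choice; the package computes them on whatever log-scale
matrix is passed, and the bundled `technical_covariates()` helper uses raw
log counts.

## The evaluations

**cis-eQTL scan.** SNPs pair with genes when within 100 kb of the TSS,
*boundary inclusive* (the rule says "within"; inclusivity is asserted at
exactly 100,000 bp). A SNP in several genes' windows goes to the closest
TSS, with equidistant ties broken by lower TSS coordinate then
lexicographic gene id — deterministic and documented rather than
arbitrary. Spearman $\rho$ uses mid-ranks; p-values use the
$t$-approximation on $n-2$ degrees of freedom for $n \ge 8$ and the exact
permutation null below that, where the approximation is poor. Missing
dosages are handled pairwise-complete, and pairs left monomorphic or with
fewer than three informative subjects are dropped with a log message.
Benjamini–Hochberg adjustment is applied across all tested pairs
(delegated to `stats::p.adjust`); discovery counts are reported at 1, 5
and 10% FDR at both pair and gene level, since either convention appears
in practice. Gene-level p-values are per-gene minima over tested cis SNPs.
Cross-dataset consistency is the Spearman correlation of shared-key
p-value vectors with a 90% Fisher-z interval.

**Co-expression.** Networks are pairwise Pearson correlations mapped to
non-negative weights — absolute value by default, since sign handling is
unspecified in standard practice and $|r|$ retains anti-correlated
co-regulation; `positive` and `shifted` transforms are available. Function
terms are filtered by dropping electronically-inferred (IEA) annotations
*first* and then applying the inclusive 30–300 size bounds — the order
matters and is tested. Label propagation solves
$(I - \alpha S)f = (1-\alpha)y$ with the symmetrically degree-normalized
$S$ and $\alpha = 0.95$ (the literature's typical strength; exposed);
degree-zero genes fall back to $(1-\alpha)y$. Evaluation is stratified
5-fold cross-validation per term, scoring held-out genes only, with
negatives taken as all genes not annotated to the term (negatives are
otherwise undefined for GO-style labels). The precision–recall area is the
step-wise (non-interpolated) sum — interpolation conventions change AUP
values, so the convention is fixed and tested against closed forms (a
single positive at rank $r$ gives exactly $1/r$).

## What the synthetic generator does and does not emulate

`generate_expression()` draws $Y = F\beta + ZB + ML + \varepsilon$ on the
log scale: known covariates with direct effects, hidden factors correlated
with the known covariates ($Z = FU + $ factor noise — precisely the regime
the HCP prior assumes), optional co-expressed gene modules sharing a
subject-level factor, and i.i.d. Gaussian noise. Defaults put the hidden
confounder near 55–65% of per-gene variance, the broad-trend regime in
which confounder correction is consequential. `generate_genotypes()`
places a configurable number of SNPs in every gene's cis window with
Binomial(2, MAF) dosages; `plant_eqtls()` adds dosage-proportional effects
to chosen genes and records the truth; `generate_function_labels()` builds
GO-like terms concentrated in modules. Each generator consumes its own
seed, so streams are independent and reproducible.

What this does *not* emulate: linkage disequilibrium between SNPs,
count-level noise (a Poisson emission layer `expression_to_counts()`
exists for exercising the preprocessing path, but the model is fitted on
Gaussian log values), isoform structure, population structure, and the
ontology's true-path semantics (terms are flat sets). Passing tests on
this generator therefore demonstrate correctness of the estimators and
the qualitative behavior of the pipeline under the model's own
assumptions — not performance on any real dataset.

## Experiment scales and expected shapes

The packaged experiments use 60 subjects and 200–250 genes with 400–500
cis pairs — sizes chosen so the full suite, including ten-seed repetitions
of both evaluations, runs in well under a minute while leaving the
qualitative contrasts unambiguous. Two shapes are asserted as seeded
majority-of-ten-seeds tests:

1. With a strong hidden confounder, 10%-FDR cis-eQTL discoveries order as
   HCP $\ge$ SVD $\ge$ ridge $\ge$ raw: hidden-covariate removal is worth
   more than known-only correction, and the prior adds a further margin.
2. With planted co-expression modules, removing 10 PCs — the setting that
   is best for the eQTL task — drags mean AUP *below* the uncorrected
   baseline, while HCP at the same capacity and penalties does not: the
   prior stops the removal from consuming module structure that merely
   happens to be broad.

Both mirror the central published contrast between unguided PC removal
and prior-guided factor removal. The second is the sharper claim: it is
the reason "how many PCs to remove" cannot be answered once for all
downstream analyses, and the reason HCP's prior is not an ornament.

## Known limitations

- One shared ridge penalty across genes (no gene-specific $\lambda$).
- No protection of effects of interest during factor estimation (the
  genotype is never shown to the normalizer; planted-effect recovery in
  tests rests on cis effects being narrow, not on explicit protection).
- $k$ and the $\lambda$s are not selected automatically; cross-validation
  on the downstream task is the intended procedure and is left to the
  user.
- The Spearman p-value's $t$-approximation is approximate under heavy
  ties at moderate $n$; the exact-permutation path applies only below
  $n = 8$.
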