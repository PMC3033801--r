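---
title: "Pathway association testing with reduced gene subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway association testing with reduced gene subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathfpc)
```

## The problem and the model

Case-control GWAS rarely explain a complex trait one SNP at a time: the
individual effects are small, and the multiple-testing burden across half a
million markers is severe. Pathway-level analysis pools markers over
biologically curated gene sets, but a pathway typically contains many genes
of which only a few are associated; a joint test over *all* genes dilutes
those few signals across a large number of degrees of freedom.

`pathfpc` implements a pathway test built around a *reduced gene subset*:

1. **Gene scores.** For gene $g_j$ with $p_j$ SNPs, the dosage block
   $X_j \in \{0,1,2\}^{n \times p_j}$ (minor-allele counts) is centered per
   SNP and projected onto the top eigenvector of its sample covariance. The
   first principal component $\mathrm{FPC}_j$ is a single score per gene,
   reducing the predictor count from $P = \sum_j p_j$ to $K$.
2. **Candidate subsets.** The binary phenotype $Y$ is regressed on the $K$
   gene scores by LASSO-penalized logistic regression,
   $\log L(\beta) - n\lambda \sum_{j\ge 1} |\beta_j|$ (intercept
   unpenalized). As $\lambda$ grows from 0, the active set shrinks from all
   $K$ genes towards empty; each distinct non-empty active set along the
   grid is a candidate subset $S_1, \dots, S_{K'}$.
3. **Selection.** Each candidate is refit by *unpenalized* maximum
   likelihood and scored by
   $\mathrm{AIC}(S) = -2\log L(\hat\beta(S)) + 2\,v(S)$ or
   $\mathrm{BIC}(S) = -2\log L(\hat\beta(S)) + \log(n)\,v(S)$, where $v(S)$
   counts genes. The minimizer is the reduced subset $S^*$ with
   $m = v(S^*)$ genes.
4. **Test statistic.** $T(G)$ is the likelihood-ratio statistic of the
   logistic model on $S^*$ against the intercept-only model. Its nominal
   reference is $\chi^2_m$, but because $S^*$ was selected on the same data
   the p-value comes from a permutation null instead: phenotype labels are
   shuffled, a subset of size *exactly* $m$ is re-selected on each shuffled
   dataset (so the permuted statistics share the $\chi^2_m$ scale), and
   $p = \#\{T(G^{(\pi)}) > T(G)\}/B$.
5. **Multiplicity.** Across pathways, each statistic is normalized by the
   mean and SD of its own permutation distribution
   ($\mathrm{NLR}$), and permutation-based FDR and FWER are computed from
   NLR exceedance counts on one shared permutation ensemble.

The package also provides the standard comparison statistics — the
most-significant-SNP test (MSS), the rank truncated product
($\mathrm{RTP}_k$, product of the $k$ smallest trend-test p-values), the
Fisher combination $-2\sum \log p_i$, and the admixture maximum likelihood
(AML) mixture fit to the signed trend statistics — all assessed with the
same phenotype-permutation machinery, plus the genotype simulator and
power/type-I-error evaluation tools used throughout the test suite.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 5000 | SNP-to-gene assignment window, base pairs, inclusive on both sides of the gene body |
| `min_genes` | 15 | minimum mapped genes for a pathway to be tested |
| `criterion` | `"bic"` | subset-selection criterion (`"aic"` or `"bic"`) |
| `B` | 200 | phenotype permutations per pathway |
| `nlambda` | 100 | log-spaced penalty grid points between $\lambda_{\max}$ and $10^{-4}\lambda_{\max}$, plus $\lambda = 0$ |
| `standardize` | `TRUE` | standardize gene scores inside the LASSO solver only (penalty fairness across genes); coefficients are reported on the original scale |
| `estimator` | `"literal"` | permutation p-value $\#\{T(\pi) > T\}/B$; `"add_one"` gives $(1+\#\{T(\pi) \ge T\})/(B+1)$ |
| `fdr_variant` | `"averaged"` | FDR numerator averaged per permutation; `"literal"` pools the raw count |
| `base_prevalence` | 0.05 | baseline disease probability of the simulator's multiplicative model |

Two conventions deserve emphasis. The FPC uses **covariance PCA on
centered, unscaled dosages** — genotypes are centered by subtracting the
per-SNP mean and never standardized (a `--standardize` style rescaling
would change the loadings; it is deliberately not applied, while the LASSO
*solver* standardization is a separate, flagged choice). The gene-score
**sign convention** (largest-|loading| entry positive) is arbitrary but
fixes reproducibility; all downstream likelihood-ratio statistics are
sign-invariant.

## Design choices where the design was open

**Phenotype model.** The selection and LR machinery needs a likelihood for
a binary trait given gene scores; logistic (Bernoulli, logit link)
regression is the standard case-control choice and is fixed throughout.

**Refit criteria.** AIC/BIC are evaluated on unpenalized maximum-likelihood
refits of each candidate subset, not on the penalized solution, because the
criterion formulas reference the maximized log-likelihood
$\log L(\hat\beta(S_j))$.

**Size-constrained permutation.** In each permuted dataset the package
re-applies *the observed selection map restricted to size m*: among the
permuted path's distinct candidate subsets with exactly $m$ genes, it keeps
the one whose unpenalized refit maximizes the likelihood — which is
precisely what the information criterion reduces to at fixed size, and
precisely what the observed $S^*$ is on the observed path given that the
criterion chose size $m$. This makes the observed and permuted statistics
exchangeable under the null conditional on $m$. The weaker alternative of
truncating the largest active set of size $\ge m$ to its $m$
largest-|coefficient| members (available as `rule = "truncate"` in
`constrained_subset()`, and used as a fallback when no grid $\lambda$
yields exactly $m$ active genes) produces stochastically *smaller* permuted
statistics and measurably inflates the type I error of the liberal AIC
variant (to about 0.08 at a nominal 0.05 in the package's null study) —
that empirical calibration failure is why the criterion-restricted rule is
the default. Candidate subsets along a LASSO path are not strictly nested,
so no nesting is assumed anywhere.

**FDR numerator.** A raw count of permutation exceedances pooled over $B$
permutations is not a rate; dividing by $B$ (the per-permutation average,
as in gene-set enrichment practice) makes the numerator an expected count
and the ratio an FDR. The averaged form is the default; the literal pooled
form is available as `fdr_variant = "literal"`. Both are capped at 1.

**Shared permutation ensemble.** FWER requires $\max_{AG}$ over pathways
*within* one permutation, which is only well-defined if all pathways see
the same shuffles. One seeded ensemble (`make_permutations()`) is therefore
shared across pathways and across methods; this also pairs replicates
correctly for McNemar comparisons between methods.

**Minor-allele determination.** Dosages are minor-allele counts with the
minor allele determined from the sample itself (frequency $\le 0.5$; exact
ties resolved to the lexicographically smaller allele). A consequence worth
knowing: a SNP whose sample MAF is exactly 0.5 may swap alleles between
datasets; round-trips through PED are exact except at such ties.

**Mapping tie-breaks.** A SNP within 5 kb of several genes is assigned by
functional category (coding > intronic > 5'utr > 3'utr), then by smallest
distance to the gene body, then by lexicographic gene id. The
distance/lexicographic tail is a package choice for the case the category
scheme leaves undetermined; it is deterministic and input-order invariant.

**AML likelihood.** The AML comparison models the signed trend statistics
as $(1-\alpha)N(0,1) + \alpha\cdot\tfrac12[N(\zeta,1)+N(-\zeta,1)]$ and
maximizes the log-LR against $N(0,1)$ by EM from a $3\times3$ multi-start
grid ($\alpha \in \{0.01, 0.1, 0.3\}$, $\zeta \in \{0.5, 1, 2\}$); the null
$\lambda = 0$ is always a competitor, so the reported statistic is
nonnegative. Correlated SNPs inflate the estimated proportion of causal
SNPs; no correction is applied, matching how the method is used as a
comparison baseline. The fit is validated in the test suite against a dense
$(\alpha, \zeta)$ grid search.

## What the simulator emulates — and what it does not

`simulate_replicate()` reproduces the published simulation design: three
pathway patterns (15 genes / 159 SNPs with 2 associated genes and 4 causal
SNPs; 35/339/4/6; 208/1957/19/39) whose causal-SNP minor-allele frequencies
and per-allele estimated relative risks are fixed pattern tables;
haplotypes drawn from a pool and paired under Hardy-Weinberg equilibrium;
disease status from a multiplicative relative-risk model
$P(\text{affected}\mid g) = \text{prev}\cdot\prod_s \mathrm{RR}_s^{g_s}$
with rejection sampling to exactly $n_\text{cases}$ and
$n_\text{controls}$; and an attenuation factor $f$ multiplying every RR to
sweep effect sizes. The combined pattern-1 relative risk is
$\prod f\cdot\mathrm{ERR}_i$: 1.46 at $f = 1$ and 1.24 at $f = 0.96$.

The one deliberate departure: the original haplotype pools were estimated
from real control samples, which cannot be redistributed. The package
substitutes parametric pools. The default LD model is a first-order
correlation chain spanning each gene with neighbour correlation $r = 0.9$
(neighbour $r^2 = 0.81$, i.e. adjacent SNPs form strong-LD groups at the
conventional $r^2 \ge 0.8$ threshold, decaying with distance). Causal SNPs
are spaced 5 loci apart, so their pairwise $r^2 \approx 0.33$ places them
in *distinct* strong-LD groups — consistent with selecting one causal SNP
per strong-LD cluster. An earlier design with several short equal blocks
per gene was rejected: it makes the first principal component structurally
unable to summarize a gene (no dominant direction), whereas a single
dominant LD structure per gene matches the empirical observation that one
PC captures most within-gene information. Two practical details follow
from Bernoulli algebra: SNPs in strong LD must have similar allele
frequencies (the attainable correlation is bounded by
$\approx\sqrt{\mathrm{maf}_1/\mathrm{maf}_2}$), so block members' MAFs are
drawn as a shared base (the causal SNP's MAF where applicable) with ±5%
jitter, and any neighbour pair whose target $r$ still exceeds its bound is
capped at 99.5% of the attainable value (`cap_r = TRUE`), exactly as
empirical LD behaves; `build_pool()` without `cap_r` rejects infeasible
combinations outright.

`assign_phenotype()` draws Bernoulli status for a fixed dosage matrix;
exact-count retention necessarily draws more individuals than any fixed
matrix holds, so it lives in a separate rejection-sampling routine used by
`simulate_replicate()`. Under the global null (no causal SNP) every
individual's disease probability equals the baseline, so retained case and
control genotypes are interchangeable pool draws; the null studies
therefore sample $n$ genotypes and attach the label vector directly, which
is distributionally identical and much faster.

Passing tests on this generator demonstrate the statistical machinery —
calibration under the null, the benefit of subset selection under sparse
alternatives, selection-quality orderings — but *not* performance on real
GWAS data: real LD is irregular and long-ranged, real MAF spectra are
skewed toward rare variants, genotypes have missingness and batch
structure, and real pathways overlap. Absolute power numbers from the
original real-data-driven pools are not reproducible here and are not
asserted anywhere; only directional properties are.

## Numerical choices

* Logistic refits use a step-halving Newton/IRLS (convergence $10^{-10}$ on
  the log-likelihood); it agrees with `stats::glm.fit` to near machine
  precision and is property-tested against it. Perfect separation (detected
  by non-convergence or $|\hat\eta| > 30$) falls back to a ridge-stabilized
  fit with penalty $10^{-8}$, with a warning.
* Linear predictors are clipped at $|\eta| \le 35$ in likelihood
  evaluations; beyond that the Bernoulli likelihood is constant to double
  precision.
* The penalized path is solved by `glmnet` over the package's grid
  (`glmnet`'s $\lambda$ coincides with the model's $\lambda$ because its
  objective is $-(1/n)\log L + \lambda\lVert\beta\rVert_1$); symmetric
  eigensolves use LAPACK via `eigen(symmetric = TRUE)`, from the
  $p_j \times p_j$ covariance when $p_j \le n$ and the $n \times n$ Gram
  matrix otherwise. Zero-variance gene blocks yield an all-zero score with
  a warning.
* Permutation re-selection under the default criterion rule scans the full
  penalty grid of the permuted path (size-$m$ candidates can appear
  anywhere, and dropping late ones measurably shifts the null); the
  `"truncate"` rule only needs the top of the grid and is fitted in
  segments from $\lambda_{\max}$ with early stopping, which the test suite
  verifies against a full-grid scan on hundreds of random instances.
  The coordinate-descent threshold is $10^{-6}$ throughout (active sets are
  stable well above it, and observed and permuted paths always share one
  threshold so the permutation map is consistent).
* The AML EM iterates in compiled code with a fused objective/E-step pass
  and stops when $\lambda$ changes by less than $10^{-4}$ (its value enters
  only permutation rank comparisons, which are orders of magnitude
  coarser); the objective is asserted non-decreasing at every iterate.
* Missing genotypes are mean-imputed per SNP before centering by default;
  an iterative rank-1 PCA imputation is available
  (`impute = "iterative"`). An all-missing SNP is an error naming the SNP.

## Problem sizes used by the shipped studies

The acceptance studies run at the following scales, chosen as the package's
desk scale: the null (type-I-error and uniformity) study uses 500
replicates of the 15-gene pattern with 300 cases + 300 controls, LD-free
genotypes and 200 permutations per replicate; the power/selection study
runs pattern 1 at $f = 1$, 1350 cases + 1350 controls (the published
sample size), 100 replicates and 100 permutations. One replicate of the
full eight-method pipeline costs roughly 2 s on a single core.

## A worked example

```{r example, eval = FALSE}
library(pathfpc)

# one simulated replicate of the small pathway pattern at full effect size
sim <- simulate_replicate(sim_pattern("pattern1"), f = 1, seed = 1)

# gene scores and the FPC_BIC pathway test with 200 permutations
gs <- build_gene_scores(sim$ds, sim$gene_map)
res <- fpc_pathway_test(gs$scores, sim$ds$y, criterion = "bic",
                        B = 200, seed = 2)
res
#> FPC_BIC pathway test: K = 15, m = 1, T = 16.985, p = 0 (B = 200)
#>   selected genes: g002

# the selected subset against the simulation truth
psr_fdr(res$subset, sim$truth$assoc_genes)
#> $psr
#> [1] 0.5
#> $fdr_sel
#> [1] 0
```

BIC has selected a single gene — one of the two truly associated ones — so
no permuted statistic reaches the observed likelihood ratio ($p = 0$ under
the literal estimator), half of the associated genes were recovered
(PSR 0.5) and nothing falsely selected (selection FDR 0). That conservatism
of BIC relative to AIC recurs throughout the selection studies.

When the subset size is fixed a priori (no data-driven selection), the
permutation p-values and the $\chi^2_m$ tail agree to within Monte-Carlo
error under the null — a useful sanity check, though not asserted strictly
since the selected-size pipeline is the supported path.

## Known limitations

* **The AIC variant is liberal under the null.** Selecting $m$ by AIC on
  the observed data and then constraining permutations to that $m$ leaves a
  conditioning bias: replicates where AIC prefers a multi-gene model have
  observed statistics that are large *because* of that preference, which
  the size-constrained null does not replicate. In the package's null study
  (15 genes, 300 cases + 300 controls, LD-free) FPC_AIC rejects at
  $\approx 0.07$–$0.08$ against a nominal 0.05, while FPC_BIC (whose
  heavier penalty rarely selects more than one gene under the null) and all
  comparison methods stay within the binomial band around 0.05; the bias
  grows with the selected size, which AIC's light penalty lets wander under
  the null. The published comparisons show the same signature in miniature
  (AIC type I error consistently above 0.05 at a larger sample size with
  real LD). Use BIC when strict type-I control matters; treat AIC as the
  liberal, high-recall selector it is shown to be in the selection
  studies.

* Absolute powers depend on the parametric LD substitute and are not
  comparable to values computed on real haplotype pools.
* The permutation p-value with the literal estimator can be exactly 0; use
  `estimator = "add_one"` when downstream procedures cannot accept zero
  p-values.
* FDR/FWER require all pathways to share one permutation ensemble; results
  from separate runs with different seeds must not be mixed.
* The restandardization refinement of the permutation null and
  quantitative-trait extensions are out of scope.
* Binary PLINK (BED/BIM/FAM), VCF input, genotype imputation and QC
  filtering are not provided; inputs are text PED/MAP or the package TSV.
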