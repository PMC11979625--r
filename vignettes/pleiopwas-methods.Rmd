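---
title: "Methods: PWAS, conditional FDR and expression validation on synthetic two-trait studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PWAS, conditional FDR and expression validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pleiopwas` implements a three-stage inference for shared genetic risk
between two related traits, working entirely from GWAS summary statistics
plus a cis-protein-weight reference:

1. **PWAS** — train cis-SNP weight models for protein abundance and score
   each gene's association with each trait by a weighted z-score.
2. **condFDR / conjFDR** — rerank one trait's variant associations within
   strata of the other trait's associations, and call shared loci at
   conjFDR < 0.01 with LD clumping, lead-SNP selection and gene mapping.
3. **Expression validation** — test candidate genes for differential
   expression between patients and controls.

Because the real inputs of such studies (case-control GWAS, brain pQTL
reference panels, postmortem expression cohorts) are restricted-access,
the package ships a seeded synthetic-data generator that reproduces the
*statistical structure* those stages assume, with planted truth so every
stage can be scored.

# The synthetic study generator

## LD model

The variant panel is split into independent blocks. Within a block of
size $k$ the reference correlation is AR(1):
$R_{ij} = \rho^{|i-j|}$, with $\rho$ = `block_rho` (default 0.8 over 200
blocks of 100 variants). The choice is deliberate: AR(1) entries have a
closed form, so every LD-dependent computation — the PWAS denominator
$w'Rw$, pruning adjacency, clump membership — can be checked against
hand arithmetic. Cross-block correlation is exactly zero.

## Genotypes

Dosages are sums of two independent haplotypes. Along a block, each
haplotype is a binary Markov chain: allele $i{+}1$ is Bernoulli with the
panel MAF as marginal and correlation $\rho$ with allele $i$. For binary
variables the conditional expectation is linear, so correlations multiply
along the chain and the dosage correlation at lag $d$ is exactly
$\rho^d$ in expectation — the same matrix the reference $R$ declares.
(A latent-Gaussian copula pushed through a binomial quantile was
considered and rejected: discretization attenuates the realized LD well
below its latent target.) Two practical consequences:

- MAFs are sorted within a block, because a correlation of $\rho$ between
  Bernoulli variables is only feasible when their frequencies are close;
  sorting makes adjacent frequencies similar and truncation of the
  adjacent correlation rare.
- Allele pairs exclude strand-ambiguous combinations (A/T, C/G), so the
  simulated summary statistics are fully usable after allele alignment.
  The ambiguity-dropping rule in `pwas_association()` still applies to
  loaded external data and is tested separately.

## Protein abundance

Each gene receives a cis window (default 100 kb) inside its block and
`n_causal_cis` causal variants with N(0,1) effects. Noise is scaled so
the realized genetic component explains exactly `h2_cis` of the abundance
variance in expectation. `h2_cis = 0` (with zero causal variants) gives
pure-noise abundance, the null for weight training. The reference cohort
defaults to 400 individuals, the scale of brain pQTL panels.

## Two traits with controlled overlap

Each variant is assigned one of four causal classes — shared, trait-1
only, trait-2 only, null — with probabilities `(pi_shared, pi1, pi2,
remainder)`. Causal effects are standardized draws
$\beta \sim N(0, \sigma_\beta^2)$; **shared variants use a single draw
for both traits**, so planted pleiotropic signals are direction-
concordant in expectation, mirroring the concordant lead-SNP z-scores
such analyses report. Per block,

$$ z = \sqrt{N}\, R\beta + \varepsilon, \qquad \varepsilon \sim
   \mathrm{MVN}(0, R), $$

i.e. effects are LD-smeared and noise is LD-correlated within blocks and
independent between traits. Traits are represented directly at the
summary-statistic level (liability-scale effects); no individual-level
case-control sampling is performed, which keeps the null distribution of
$z$ exactly standard normal. The effect-size distribution is a modelling
convention (mixture normal), not an empirical estimate.

Extreme p-values are floored at 1e-300 so conversion of large $|z|$ never
underflows to zero, which would break log-scale binning.

## Expression

Expression matrices are log-scale unit-variance Gaussian noise with
planted per-gene, per-group mean shifts expressed in baseline SDs. The
generator accepts arbitrary group layouts (balanced 10 vs 10, or
unbalanced designs such as 18 controls vs 5 patients and 12/7/10
three-group cohorts).

## What the generator does *not* emulate

Genotyping error, imputation uncertainty, population stratification,
sample overlap between the two GWAS (which correlates their null noise),
MAF-dependent architecture, trans effects, and count-level RNA-seq noise.
Passing tests therefore demonstrate correctness of the statistical
machinery under its stated model, not robustness to those artefacts of
real data.

# PWAS stage

## Weight models

Four models per gene, fitted on the training genotypes $X$ and abundance
$y$:

- `top1`: the single SNP with the largest $|$marginal correlation$|$;
  weight = its OLS slope.
- `blup`: ridge regression, implemented as `glmnet` with $\alpha = 0$ and
  the penalty chosen by cross-validation. (A mixed-model BLUP solver
  would estimate the same shrinkage target; ridge-by-CV is the standard
  equivalence and avoids a REML dependency.)
- `lasso`: $\alpha = 1$; `enet`: $\alpha = 0.5$.

Every model is scored by k-fold cross-validated $R^2 = 1 -
\mathrm{SSE}/\mathrm{SST}$ on held-out predictions (prevalidated
predictions at `lambda.min` for the penalized models; an explicit fold
loop for `top1`, re-selecting the top SNP inside each training fold so
selection optimism is not leaked). `best_model` is the cv-$R^2$ argmax
among models with a nonzero weight vector; an all-zero lasso path is
excluded with a warning rather than chosen. Constant genotype columns are
dropped; constant abundance produces a flagged degenerate model, never an
error. A Bayesian sparse mixed model (a fifth family some weight
pipelines offer) is intentionally not included; the model set is a named
column dimension, so adding one is additive.

## Association statistic

For weights $w$ over the cis window and GWAS z-scores $z$,

$$ z_{\mathrm{PWAS}} = \frac{w^\top z}{\sqrt{w^\top R w}} . $$

The quadratic-form denominator is what makes the weighted linear sum a
proper z-score under the null: if $z \sim \mathrm{MVN}(0, R)$ then
$z_{\mathrm{PWAS}} \sim N(0,1)$ for any fixed $w$. A plain "linear sum of
z × weight" without the denominator is not scale-free and has no null
calibration; the normalized form is what the established TWAS/PWAS
statistic computes. GWAS alleles are aligned to the weight reference
first (swapped alleles flip the z sign; strand-ambiguous SNPs are dropped
by default since strand cannot be resolved without metadata); weights of
SNPs absent from the GWAS are zeroed and the denominator recomputed on
the present subset; genes with under 50% SNP overlap (configurable) or a
numerically zero denominator are skipped with explicit reasons.

## Significance

The proteome-wide significance rule is configurable: BH-FDR at 0.05
(default) or Bonferroni, with the test count `m` allowed to exceed the
scored genes (e.g. the full proteome size when only a subset was
testable). Published PWAS tables do not always state their rule — the
reported p-values sometimes exceed a strict Bonferroni bound — so the
rule is a parameter rather than a guess. The "overlap" set is the
intersection of the per-trait significant gene lists.

# Conditional FDR stage

## Conditional Q-Q curves

For strata $s \in \{1, 0.1, 0.01, 0.001\}$ of the conditioning trait's
p-values, the primary trait's p-values among variants with $p_2 \le s$
are plotted against the uniform expectation $-\log_{10}(i/(n{+}1))$.
Nested leftward deflection with stricter strata is the visual signature
of cross-trait enrichment. Strata with fewer than 100 variants are
emitted but flagged low-count.

## The condFDR estimator

On a grid over $(-\log_{10} p_1, -\log_{10} p_2)$ — 101 nodes uniform on
$[0, 10]$ plus one overflow node at the p-value floor — each node with
thresholds $(p_1, p_2)$ receives

$$ \widehat{\mathrm{cFDR}}(p_1 \mid p_2) =
   \frac{p_1 \, W(p_2)}{W(p_1, p_2)} \wedge 1, $$

where $W(p_2)$ is the weighted count of variants passing the conditioning
threshold and $W(p_1,p_2)$ the weighted count passing both. This is the
empirical-Bayes conditional FDR: the numerator is the expected null count
among conditioned variants, the denominator the observed count. Cells
with an empty denominator take the cap value 1. Because the raw counting
estimator is nonmonotone under sparsity, each conditioning column is then
made nonincreasing in $-\log_{10} p_1$ by a cumulative minimum — the
monotone envelope the method family enforces.

Numerical conventions: $-\log_{10} p$ values within $10^{-9}$ of a grid
node are snapped onto it, in both binning and interpolation, so p-values
that are exact powers of ten behave node-exactly; per-variant assignment
is bilinear in $(-\log_{10} p_1, -\log_{10} p_2)$ and clamped to
$[0, 1]$. The 101-node resolution (0.1 in $-\log_{10} p$) trades grid
granularity against count sparsity per cell.

## Pruning weights

Counting every variant would let large LD blocks dominate the empirical
CDFs. `random_prune()` repeats a greedy random-order thinning (keep a
variant if its $r^2$ with everything already kept is at most `r2_max`,
default 0.1) for `n_iter` = 100 iterations and weights each variant by
its inclusion fraction. With `r2_max = 1` all weights are 1 and the
lookup equals the unweighted one exactly.

## conjFDR, loci, genes

The conjunctional FDR is the maximum of the two reciprocal condFDR
values, a conservative bound on the posterior probability of being null
for either trait; the significance threshold is 0.01. Passing variants
are clumped greedily in conjFDR order (ties: smaller $p_1$, then variant
id, for determinism): each unassigned variant seeds a locus and absorbs
unassigned passing variants with $r^2 \ge$ `r2_clump` (default 0.1).
Clumping is LD-based only — no distance merging, which would collapse
nearby-but-distinct loci of the kind real shared-locus tables keep
separate. The seed is the lead SNP (member-minimal conjFDR). Genes are
mapped by interval containment of the lead position (configurable flank,
default 0; overlapping genes all map; an empty hit is reported as
intergenic), and lead direction concordance is the sign agreement of the
two z-scores, with zero z flagged discordant-with-warning. No genomic
region is excluded by default; an exclusion list is configuration.

# Expression validation stage

Normality is pre-checked with a Kolmogorov-Smirnov statistic against a
normal with the sample's estimated mean and SD. Estimated parameters make
the textbook KS reference anti-conservative, so the p-value is calibrated
Lilliefors-style by a seeded parametric bootstrap (1000 draws with
re-estimated parameters per draw; smoothed exceedance fraction). Constant
samples get p = 0 with a degeneracy flag.

Two groups are compared by Welch's unequal-variance t-test (which equals
the pooled t when the design is balanced with equal variances); three or
more groups by classic one-way ANOVA, with two-group input rejected in
favour of the t-test. Group means are always reported so the direction of
a shift (e.g. disease downregulation) is checkable, and calls use raw
p < 0.05 to match single-gene validation practice, with BH-adjusted
values reported alongside for multi-gene screens without asserting which
the validation intends.

# Pipeline and problem sizes

`run_pipeline()` chains the stages on one scenario and reports the PWAS
overlap set, the shared loci with mapped genes, the DE calls, and — when
a three-way gene is planted (cis-regulator + shared causal variant +
downregulated transcript) — whether all three stages flagged it. The
planted lead effect is parameterized as the expected lead z-score
(default 8), and the expression shift in case-SD units (default −2).

Default scenario sizes were chosen once for desk-scale work: 20000
variants in 200 blocks, 50 genes, 400 training samples, GWAS N = 50000.
The test suite uses 20-seed replicates at these sizes for calibration and
recovery checks, 300–500 genes for the PWAS null distribution, 1000 genes
for DE calibration and 100 replicates for DE power; the whole suite runs
in a few minutes on one core.

# Known limitations

- The condFDR estimator shares the usual limitations of the empirical
  method family: it is a pointwise empirical-Bayes bound, not a joint
  model; sample overlap between the two GWAS would bias it and is not
  modelled.
- Weight models are linear and cis-only; no fine-mapping or
  colocalization is performed on PWAS hits.
- Gene mapping is positional only (no eQTL or functional linking).
- The DE stage tests normalized values per gene; it is not a count-model
  RNA-seq pipeline.
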