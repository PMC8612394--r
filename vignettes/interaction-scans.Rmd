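---
title: "Testing SNP-SNP interactions on old-age survival and aggregating them into interaction polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing SNP-SNP interactions on old-age survival and aggregating them into interaction polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episurv)
```

## The scientific problem

Single-locus association studies of human longevity often fail to confirm
genes whose role in lifespan regulation is well established in model
organisms. One explanation is that such genes act through *interactions*:
a stress-sensor gene and a downstream cell-fate regulator may jointly
shape survival even when neither shows a marginal effect. `episurv`
implements the statistical machinery for testing this hypothesis in
case-control survival data:

1. a dichotomous **survival trait** — cases survived to age 85 or beyond,
   controls died (or were last followed up) between ages 75 and 85;
2. per-pair **logistic regression with an interaction term**,
   $$\operatorname{logit} P(\text{case}) = \beta_0 + \beta_1 g_1 +
   \beta_2 g_2 + \beta_{12}\, g_1 g_2 + \boldsymbol\gamma^\top \mathbf x,$$
   where $g_1, g_2 \in \{0,1,2\}$ are additive minor-allele counts and
   $\mathbf x$ are observed covariates (education, smoking, sex, PC1–PC5);
   the interaction coefficient $\beta_{12}$ is the quantity of interest;
3. **LD clumping** of the many correlated candidate pairs down to
   independent representatives before Bonferroni correction;
4. the **SNP-specific Interaction Polygenic Risk Score (SIPRS)**, which
   aggregates, for one fixed SNP, the many genome-wide partner pairs whose
   interaction P-value passes a threshold into a single per-individual
   score.

Because individual-level cohort data of this kind are access-restricted,
the package ships a calibrated synthetic generator so that every stage is
testable end to end.

## The synthetic cohort generator

### What it emulates

The default configuration (`sim_config()`) mirrors a two-gene candidate
study at the scale of a large ageing cohort: 6142 individuals with an
expected 2564 cases and 3578 controls; one gene of 63 SNPs partitioned
into eight LD blocks whose minor allele frequencies (0.06, 0.03, 0.47,
0.03, 0.05, 0.44, 0.02, 0.13) span the 0.02–0.47 range typical of such
panels; a second gene of 8 SNPs in one block at MAF 0.14; binary
covariates at prevalences 0.94 (education), 0.57 (smoking), 0.569
(female); five i.i.d. standard-normal principal components; no main
effects; and a single cross-gene interaction of log-odds
$\beta_{12} = 0.60$ between the first SNP of each gene. These values are
the study conditions the package is tested under, not tuning knobs.

### LD by latent-Gaussian thresholding

Each haplotype's allele at SNP $j$ is the indicator
$X_j = \mathbf 1\{Z_j > \Phi^{-1}(1 - \mathrm{MAF}_j)\}$ of a standard
normal exceeding the frequency-matching threshold; a genotype is the sum
of two independent haplotypes, so Hardy-Weinberg proportions hold by
construction. Within an LD block the latent normals are correlated, and
the latent correlation $\rho$ is **calibrated** by a monotone root search
(`uniroot` on the tetrachoric-type map $\rho \mapsto
\operatorname{corr}(X_1, X_2)$, evaluated by one-dimensional quadrature of
the bivariate normal orthant probability) so that the *realised genotype*
$R^2$ matches the block target. Because the two haplotypes are i.i.d.,
the genotype correlation equals the haplotype allele correlation, so one
calibration serves both.

Two loci with unequal MAFs cannot be perfectly correlated: the
comonotone coupling bounds the allele correlation at
$r_{\max} = \frac{\min(p_1, p_2) - p_1 p_2}
{\sqrt{p_1 q_1 p_2 q_2}}$. A block target above $r_{\max}^2$ is rejected
with the attainable bound in the message (`max_attainable_r2()`); a
target of exactly 1 at equal MAFs shares a single latent variable and
yields identical genotype columns.

What the generator does **not** emulate: recombination-map-driven LD
decay, population structure beyond i.i.d. PCs, sex chromosomes,
genotyping-intensity artefacts, and informative missingness (missing
calls are MCAR at `missing_rate`). Passing tests therefore demonstrate
correctness of the statistical machinery under a clean generative model,
not robustness to the full messiness of array data.

### Trait, ages and exclusions

The case indicator is Bernoulli with the logistic model above; when no
intercept is supplied it is calibrated by root search so the *expected*
case fraction equals the configured target (2564/6142 by default). Cases
receive a lifespan of 85 plus an exponential excess with mean 4 years;
controls an age uniform on [75, 85) — the analysis only uses the window,
so any within-window distribution would do, and uniform is the neutral
choice. A configurable `exclude_fraction` plants ages in [60, 75) to
exercise the exclusion path. Missing genotypes contribute their expected
value $2 \times \mathrm{MAF}$ to the linear predictor, so missingness
attenuates nothing in expectation.

A single master seed is expanded into fixed per-stage substreams
(genotypes, covariates, trait, missingness, sample splitting), so
identical configurations reproduce byte-identical outputs and individual
stages can be regenerated independently.

## Quality control

`union_qc()` runs two full threshold protocols on the same input
snapshot and keeps the **union** of survivors, separately for individuals
and SNPs — an individual or marker passing either protocol stays. Both
protocols default to the same standard thresholds (per-individual
missingness 5%, heterozygosity outliers beyond 3 SD of the observed
heterozygous-call fraction, any of PC1–PC5 beyond 8 SD, MAF < 1%,
per-SNP missingness 5%, exact HWE P < 1e-7); the second protocol is a
freely configurable second `qc_thresholds()` instance, since the union
mechanism — not any particular second threshold set — is the reproducible
content. All filter statistics are computed on the pre-filter snapshot
and applied jointly, so filters are order-independent. The
heterozygosity statistic is the raw heterozygous-call fraction (not an
F-statistic): it needs no external allele-frequency reference and is the
directly observable quantity. The sex-mismatch check is a stub that
warns and passes: it requires sex-chromosome data the generator does not
model. The HWE test is the exact conditional test (enumeration over
heterozygote counts given allele counts) rather than chi-square, because
the QC cut sits at P < 1e-7 where the chi-square approximation is
unreliable for rare alleles.

## The interaction scan

The fitting engine (`fit_logistic()`) is a self-contained IRLS
maximum-likelihood routine returning the observed-information
covariance. Numerical choices: convergence when the maximum absolute
score drops below 1e-8 or the relative log-likelihood change below
1e-10, at most 100 iterations; IRLS weights floored at 1e-10; complete
separation guarded by flagging any fit with $|\hat\beta| > 15$ as
non-converged instead of reporting an unstable P-value; rank-deficient
designs refused with the collinear columns named. Tests verify agreement
with an independent reference ML implementation to six significant
digits.

Per pair, `test_pair()` drops rows with a missing genotype, covariate or
label (complete-case per fit; `n_used` is recorded), requires at least
`min_cell = 5` individuals carrying minor alleles at both loci, and
reports the 1-df **likelihood-ratio** P-value for $\beta_{12}$ by
default. The LRT is the default because the interaction framework is
likelihood-based; the Wald test is available via
`scan_config(test = "wald")` and agrees asymptotically. Genotypes enter
additively with the interaction as the product of codes — the standard
first interaction model. Marginal P-values `p1`/`p2` come from separate
single-SNP models (SNP + covariates), matching how a standalone
single-locus analysis of the same panel would be run, rather than from
the joint model's main-effect terms. Sex-stratified analyses subset the
cohort and drop `sex` from the covariates (`sex_stratified_scan()`).

Two designs are provided: `cross_gene_scan()` enumerates all |A| × |B|
candidate pairs between two genes, and `fixed_snp_scan()` pairs one
fixed SNP against every other marker, keeping the fixed SNP's main
effect in every model.

## Clumping

LD between SNPs within each gene makes the candidate pairs redundant.
`cluster_gene()` partitions a gene's SNPs by greedy
significance-seeded clustering: pairs are ranked by interaction P-value
(ties by rsid), the seed of each cluster is the unassigned SNP in the
best unconsumed pair, and the cluster absorbs every unassigned SNP with
$R^2 \ge$ threshold (0.1 by default) to the seed. The algorithm is the
familiar clump-style greedy pass: the threshold and the
smallest-P-per-region representative rule determine the outcome, the
greedy order makes it deterministic and oracle-checkable against
brute-force per-cell minimisation. SNPs are clustered *per gene* (the
natural reading of LD regions within each gene); clumping at the level
of pairs directly is a noted alternative that is not implemented. LD is
measured as squared Pearson correlation of genotype codes on the
analysis cohort (cases and controls combined), pairwise-complete; no
external reference panel is used. `select_representatives()` keeps the
smallest-P pair per cross-cluster cell, and the Bonferroni correction
divides $\alpha$ by the number of cells.

## SIPRS

`build_index()` aggregates the pairs of a fixed-SNP scan with
$p_{12} \le$ threshold. The published construction it follows defers
the exact weighting to earlier work, so both natural forms are
implemented and neither is asserted as canonical:

* `weighting = "beta"` (default): $s_i = \sum_k \hat\beta_{12,k}\,
  g_{i,\text{fixed}}\, g_{i,k}$ — the direct interaction analogue of a
  weighted PRS, using both positive and negative associations;
* `weighting = "count"`: the number of included pairs at which the
  individual carries minor alleles at both loci (a genetic-dose-style
  count).

Missing genotypes contribute zero to the sum. Scores are standardised
to zero mean and unit variance before evaluation. `evaluate_index()`
fits label ~ score + covariates, reporting the 1-df LRT P-value for the
score, the **Nagelkerke pseudo-R² increment** of the score over the
covariate-only model (both measured against the intercept-only null;
McFadden available via `r2_method`), and the ROC AUC of the fitted
probabilities with a DeLong 95% CI. The increment form is chosen
because "variance explained by the index" should not be credited with
what the covariates already explain. The default nine-point threshold
grid (5e-5 … 5e-2, `siprs_grid()`) is a standard log-spaced PRS sweep
containing every threshold such analyses commonly print; it is
config-overridable.

**Selection bias.** Evaluating an index on the same data that selected
and weighted its pairs is anti-conservative under the null: the test
suite demonstrates this directly, with an in-sample rejection rate at
the 5% level far above nominal under a 40-partner null scan. The package
therefore offers `siprs_analysis(split_sample = TRUE)`, which scans on
a random half and scores/evaluates the held-out half; the suite shows
this restores uniform P-values and chance-level AUC. In-sample
evaluation reproduces the historical design and remains the default,
but split-sample mode is recommended whenever the P-values are to be
interpreted.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to keep the full suite
around a minute while leaving the statistical assertions sharp: the
pair-count/clumping fixture uses the full 63 + 8 SNP structure at
n = 1500 (counts and block recovery do not depend on cohort size);
null calibration uses 1000 pairs at n = 2000; parameter recovery uses
200 replicates at the full n = 6142; the SIPRS null study uses 100
replicates of n = 600 with 40 partner SNPs. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch
under a caller-supplied seed.

## Known limitations

* The generator's block-exchangeable LD is idealised; real panels show
  LD decay and inter-block leakage, which mainly affects how many
  clusters clumping yields, not the correctness of the representative
  rule.
* Control ages are only window-constrained; time-to-event (Cox)
  modelling and competing risks are out of scope.
* Individuals alive at last follow-up inside the control window are
  treated as controls, faithfully reproducing the trait definition this
  package implements; some would have reached 85. The
  `trait_config(alive_controls = FALSE)` switch excludes them for
  sensitivity analyses.
* No relatedness correction, mixed models, genotypic (non-additive)
  interaction codings, imputation, or dosage formats.
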