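---
title: "Benchmarking SNP feature selection against polygenic scores: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking SNP feature selection against polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`prsfs` implements a leakage-free protocol for asking a practical question
in complex-disease genetics: when predicting a dichotomous phenotype such as
coronary artery disease from genotypes and clinical risk factors, do compact
machine-learning-selected SNP panels match or beat genome-wide polygenic
risk scores? Because biobank genotypes are access-controlled, the package
ships a synthetic cohort generator with known ground truth, so every stage —
quality control, per-fold association scans, feature selection, polygenic
scoring, classification — is testable end to end. This vignette records the
models, the tunable parameters, and the design decisions that were genuinely
open.

## The synthetic cohort

**Genotypes.** Each variant has an ancestral allele frequency drawn
uniformly from `maf_range` (default 0.05–0.5). Subpopulation frequencies
follow the Balding–Nichols model, `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, with
divergence `fst` (default 0.02, a mild within-continental-ancestry level;
the Hudson estimator over simulated variants recovers the configured value,
which is how the generator is validated). Linkage disequilibrium comes from
a latent-Gaussian scheme: per haplotype, a standard AR(1) field with
adjacent-variant correlation `within_block_corr` (default 0.8) is
thresholded at the frequency quantile, so marginal frequencies are exact
while adjacent dosages correlate; blocks (default 100 of 100 kb each) are
independent, which keeps windowed LD pruning exercised across block
boundaries. Positions are uniform within blocks on one chromosome.

**Phenotype.** The liability-threshold model: liability is the sum of a
genetic part (planted causal variants with equal-magnitude, random-sign
effects on standardized dosages, rescaled so the realized genetic variance
equals `h2_liability`, default 0.5 over 20 causal variants), a covariate
part, and a Gaussian residual topping total variance up to 1. Status is 1
when liability exceeds the `1 - prevalence` quantile (prevalence default
0.3, matching a case-enriched analysis cohort rather than population
prevalence). Rescaling to the realized variance (rather than the expected
one) makes recovery tests unambiguous even when a causal variant lands in a
strong-LD block.

**Risk factors.** Age, BMI, lipids and systolic blood pressure are
Gaussian; sex, smoking and diabetes Bernoulli; genotyping batch and
assessment centre uniform categorical with no liability effect. Marginals
follow a middle-aged European cohort (age 56.5 ± 8.1 y, BMI 27.4 ± 4.8,
HDL 1.4 ± 0.4 mmol/L, ...), and a Gaussian copula carries modest
correlations (e.g. HDL–triglycerides −0.4, BMI–diabetes 0.3). Liability
effects are small and signed as epidemiology suggests (HDL protective).
These distributions are artifact choices — the real cohort gives no
generative model — and they are versioned in `sim_config()`.

**What the generator does not emulate:** imputation dosages and INFO
scores, realistic recombination maps, rare-variant architecture,
X-chromosome inheritance, and pedigree structure beyond exact duplicates.
Tests passing on this generator show the *protocol* is correct and
calibrated; they do not certify performance numbers on real biobank data.

## Quality control

Variant filters run in a fixed, recorded order — missingness > 20%,
MAF < 1%, minor allele count below `mac_min`, Hardy–Weinberg exact
p < 1e-25 — because removal counts depend on order. The HWE test is the
exact conditional test (sum of probabilities of genotype configurations no
more likely than the observed one, given allele counts), computed on all
samples, as association tooling does by default. Sample missingness uses
the same 20% cut, strictly.

LD pruning slides a 500 kb window advanced by 25 variants; within a window,
while any retained pair has squared dosage correlation above 0.1, the
lower-MAF member is removed (ties to the later position) — the pairwise
convention implied by those parameters — and a final verification sweep
guarantees no retained pair within the window span violates the threshold.

Relatedness uses the KING-robust between-family estimator,
`phi = (N_het,het − 2 N_opposite-homozygote) / (N_het(i) + N_het(j))`,
chosen because it is the biobank standard and analytically forced to 0.5 on
duplicates. The default threshold is the third-degree cutoff 0.0442. One
scale caveat decided up front: the estimator's null spread shrinks like
`1/sqrt(markers)`, and at simulation scale (hundreds to a few thousand
markers, versus the >100k used in practice) the 0.0442 cut sits inside the
noise band, so the workflow and acceptance runs use the first-degree cutoff
0.177 — far above simulation-scale noise, far below the duplicate value
0.5. Greedy removal drops the member of a flagged pair involved in more
flagged pairs (ties to the later sample), until no pair exceeds the cut.

QC and pruning are applied once to the full cohort before cross-validation;
PCA, association scans, feature selection and PRS construction are per
fold. This matches the protocol's sequencing (a single pruned variant pool
feeding the CV loop) and keeps the leakage surface where it matters: in the
fitted statistics, not in marginal variant bookkeeping.

## Association scans and covariates

The per-SNP scan is additive-dosage logistic regression with the full
covariate block (risk factors, batch and centre one-hot encoded, and the
training fold's principal components), Newton-iterated to gradient
tolerance 1e-8 with a 25-iteration cap, warm-started from the
covariate-only fit; p-values are Wald, matching standard GWAS tooling.
Non-converged or separated SNPs carry a sentinel p of 1 and a flag, and are
ranked last rather than Firth-corrected — simplicity over rescue, recorded
per variant. Fisher's allelic exact test (two alleles per sample, two-sided
by hypergeometric enumeration) provides the unadjusted univariate scan; the
odds ratio is the sample cross-product with a Haldane 0.5 correction on
empty cells, flagged.

Which statistic feeds what: the univariate feature-selection ranking uses
the Fisher scan (the protocol's "association analysis" selection), while
PRS effect sizes and thresholds use the covariate-adjusted logistic betas.
Both are available and configurable (`fs_stat`).

Genotype PCA standardizes dosages by `(g − 2p)/sqrt(2p(1−p))` after
per-variant mean imputation — the standard genotype scaling — and takes a
truncated SVD (exact below 600 on the short side, randomized subspace
iteration with two power steps above it, deterministic under its seed).
Signs follow the largest-magnitude loading. Held-out samples are projected
with training-fold frequencies and loadings only. The covariate block is
screened once by variance inflation (`VIF_j = 1/(1 − R²_j)`, iterative
removal above 10) before entering any fold.

## Feature selection

Three strategies produce per-fold rankings truncated at the top-k grid
(default 5–500):

* **Univariate:** ascending association p, ties by descending `|beta|`,
  then identifier.
* **mRMR** (difference criterion): first pick maximizes relevance
  `I(x; y)`; later picks maximize `I(x; y) − mean I(x; s)` over the
  selected set, with plug-in mutual information in nats on raw genotype
  categories against binary status, complete cases, no pseudocounts. The
  greedy pool is pre-reduced to the top 500 candidates by relevance, which
  keeps the quadratic redundancy term tractable per fold without changing
  which variants can win early picks. Missing calls are replaced by the
  rounded variant mean so categories stay categorical.
* **Random forest:** impurity-decrease importances from a 500-tree forest
  with at most 35 candidate features per split, seeded, ties by identifier.

Feature-selection forests see genotypes only; risk factors and PCs join at
the classifier stage, so selected panels stay purely genomic and the
stability analysis compares like with like.

## Polygenic scores

* **Clumping + thresholding:** greedy p-ordered clumping (r² 0.1 within
  250 kb — defaults exposed in config, as the protocol leaves them
  unstated) followed by a p-threshold grid from 5e-8 to 1; weights are the
  clumped logistic betas.
* **Penalized summary-statistic regression:** per LD block, minimize
  `(1−s) βᵀRβ + s βᵀβ − 2βᵀr + 2λ‖β‖₁` by cyclic coordinate descent (unit
  diagonal makes each update one soft-threshold); the objective is asserted
  nonincreasing every sweep, convergence at max coordinate change < 1e-8,
  10 000-sweep cap. `r` is the training-fold dosage–status correlation and
  `R` the training-fold block correlation matrix (blocks of ≤100 adjacent
  variants).
* **Infinitesimal prior:** the closed form
  `β = (R + M/(N h²) I)⁻¹ β̂` per block, with `h²` a configuration value
  (default 0.5). This deterministic shrinkage stands in for Gibbs-sampled
  infinitesimal models at desk scale: it preserves the "genome-wide
  shrinkage PRS" role in the comparison while remaining exactly testable
  against a dense solve.

Hyperparameters (`p` threshold; `λ, s`) are chosen by AUC on a seeded 80/20
split inside the training fold — an explicit rule standing in for "tuned
within the training set", preventing test-fold contact. Standardized-scale
weights are mapped to the dosage scale by dividing by the training dosage
standard deviation. Every model records its training fold and sample ids;
scoring a sample contained in the model's own training fold raises a hard
error.

## Cross-validation and evaluation

Folds are stratified by (status, sex): seeded shuffle within each stratum,
then round-robin, so per-stratum counts differ by at most one. Controls may
first be subsampled to a 1:1 case:control ratio. AUC uses the Mann–Whitney
formulation with half-credit ties.

Classifiers: logistic regression fitted as L2-regularized maximum
likelihood with penalty `1/n` (the equivalent of common solver defaults;
plain ML for a single feature), lasso-logistic with the penalty chosen on a
seeded inner 80/20 split over the glmnet path, an RBF-SVM with cost 1 and
kernel width `1/p` (library defaults — the protocol prints no values, and
tuning the SVM over the all-SNP set would dominate runtime for a model the
comparison treats as a baseline), and a 500-tree probability forest with a
35-feature split cap. Feature blocks are imputed with training-fold means;
PCs accompany risk factors wherever risk factors enter (the genotype-only
baseline gets neither).

The default cell layout mirrors the comparison's figures: risk factors
alone; all pruned SNPs; each PRS alone under logistic regression and with
risk factors; each top-k panel with risk factors and PCs under lasso, SVM
and forest. Stability is the mean pairwise top-k overlap percentage across
folds (an explicit formalization of "percentage of overlap"; an
all-folds-common variant is available behind a flag), selection frequency
counts appearances across folds with a stable set at ≥5 of 10 (the
inclusive reading of the protocol's two phrasings, configurable), and the
consensus is the intersection of the three methods' stable sets.

## Numerical and scale choices

Problem sizes used by the shipped analyses and checks were chosen so a
laptop-class single core completes them comfortably: the workflow cohort is
1 500 × 1 500; the permuted-label null runs at 2 000 × 2 000 with all four
classifiers; parameter recovery at 4 000 × 5 000 (one scan per method, plus
a 10-fold benchmark on the pruned panel); the consensus-stability replicate
study at 1 200 × 1 200 over ten seeds, a size at which the consensus
property is already stable while ten full replicates stay affordable.
P-value calibration uses 5 000 independent null SNPs. Determinism is
end-to-end: every stochastic step derives its stream from the master seed,
and repeated runs are bitwise identical.

Known limitations: the simulator's LD is blocky by construction, so
proxy-credit analyses (causal *or same-block* recovery) are cleaner than
real fine-mapping; the infinitesimal PRS is a closed-form simplification of
sampled infinitesimal models; Firth correction, mixed-model association,
rare-variant tests and cross-ancestry portability are out of scope.

One limitation deserves emphasis because the ground-truthed simulations
expose it directly: *stable selection does not imply causality*.
Cross-validation folds share about 90% of their samples, so the cohort's
strongest null associations rank inside the top-k consistently across
folds — and across all three selection methods, since univariate p, mutual
information and forest importance all track marginal association. On
planted-signal cohorts the cross-method consensus therefore reliably
contains the causal blocks *plus* a comparable number of reproducibly
selected null variants (at 4 000 × 5 000 with 20 causal variants, roughly
half the consensus falls outside causal LD blocks). Consensus panels
should be read as "reproducibly predictive in this cohort", with causal
status left to replication and functional follow-up.
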