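# prsfs

Can a compact, machine-learning-selected panel of SNPs predict a complex
disease as well as a genome-wide polygenic risk score? `prsfs` is an R
package plus analysis workflow that answers this question the careful way:
a stratified 10-fold cross-validation harness in which quality control is
done once, but *every* fitted statistic — genotype principal components,
covariate-adjusted association scans, feature-selection rankings, polygenic
score weights, classifier parameters, imputation means — is recomputed on
training folds only and evaluated by AUC on held-out folds. It is aimed at
statistical geneticists and ML practitioners who want to benchmark
SNP-selection strategies against polygenic scores without data leakage, and
at method developers who need a fully synthetic, ground-truthed test bed.

Because real biobank genotypes are access-controlled, the package includes
a first-class synthetic cohort generator: biallelic SNPs with a realistic
MAF spectrum, block LD from a thresholded latent AR(1) Gaussian,
Balding–Nichols population structure, correlated clinical risk factors
(age, sex, BMI, lipids, blood pressure, smoking, diabetes), planted
duplicate samples, and a binary phenotype from the liability-threshold
model: status is 1 when

    L = sum_j beta_j g*_j  +  sum_c gamma_c z_c  +  e   >   Phi^{-1}(1 - K)

with standardized dosages `g*`, planted effects scaled so the genetic
variance equals `h²`, covariate effects `gamma`, Gaussian residual `e`
topping Var(L) to 1, and prevalence `K`.

## What is implemented

| Stage | Methods |
|---|---|
| QC | MAF / missingness / MAC filters, Hardy–Weinberg exact test, windowed LD pruning (500 kb / step 25 / r² 0.1), KING-robust kinship with greedy relatedness removal |
| Association | per-SNP covariate-adjusted logistic regression (Wald p, C++ Newton scan), Fisher's allelic exact test, genotype PCA, VIF covariate screening |
| Feature selection | univariate p-value ranking, greedy mRMR (mutual information, difference criterion), random-forest impurity importance; top-k grids |
| Polygenic scores | clumping + p-thresholding, per-block L1-penalized summary-statistic regression (coordinate descent), infinitesimal-prior closed-form shrinkage |
| Evaluation | stratified folds, control balancing, logistic / lasso / RBF-SVM / random-forest classifiers, Mann–Whitney AUC, selection-stability and cross-method consensus analysis |

## Worked example

```r
library(prsfs)

cfg <- sim_config(n_samples = 800, n_variants = 600, n_blocks = 30,
                  n_causal = 10, h2_liability = 0.5, prevalence = 0.3,
                  missing_rate = 0.02, seed = 42)
coh  <- simulate_cohort(cfg)
prep <- prepare_dataset(coh$genotypes, coh$phenotypes,
                        qc_thresholds(mac_min = 10, kinship_max = 0.177),
                        seed = 42)
prep$genotypes
#> genotype_matrix: 470 samples x 161 variants (2.01% missing)

rep <- run_cv_pipeline(prep$genotypes, prep$phenotypes,
                       cv_config(n_folds = 5, n_pcs = 4, seed = 1,
                                 k_grid = c(10, 20),
                                 models = c("lasso_logistic"),
                                 prs_methods = c("pt", "inf"),
                                 stability_k = 20, stable_threshold = 3))
print(rep)
#> cv_report: 5 folds, 60 cells
#>   feature_set          model       auc
#>      all_snps lasso_logistic 0.5736648
#>  risk_factors lasso_logistic 0.6281878
#>    top10_gwas lasso_logistic 0.7041770
#>    top10_mrmr lasso_logistic 0.6912190
#>      top10_rf lasso_logistic 0.6836096
#>    top20_gwas lasso_logistic 0.6893908
#>       prs_inf       logistic 0.5791584
#>     prs_pt_rf       logistic 0.6844949
#>  ...
#> consensus variants: snp00123, snp00208, snp00246, ...
```

Reading the table: on this planted-signal cohort (10 causal variants,
liability h² = 0.5), compact selected panels plus risk factors (AUC ≈
0.68–0.70) beat the risk-factor baseline (0.63), the all-SNP model (0.57)
and every PRS alone (0.58–0.60) — the qualitative pattern the protocol is
built to measure. The oracle ceiling (AUC of the noise-free liability) is
what separates "the method is weak" from "the data has no more signal".

The per-cell table (`cv_cells(rep)`) holds one held-out AUC per fold ×
feature set × model; `rep$stability` gives the pairwise top-k overlap
percentage per method, `rep$frequency` the per-variant selection counts,
and `rep$consensus` the variants every selection method ranked into its
stable set. On planted-signal simulations the consensus falls inside the
causal LD blocks, genotype-augmented models beat the risk-factor-only
baseline, and with permuted labels every cell's AUC collapses to ~0.5 —
the pipeline's built-in leakage alarm.

The numbered drivers under `analysis/` run the full narrative on a
1500 × 1500 cohort — simulate, QC, scan, select, score, benchmark,
stability — writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_quality_control.R
# ... through 07_stability_consensus.R
```

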