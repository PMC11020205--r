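#!/usr/bin/env Rscript
# Stage 5: the three polygenic-score constructions on a single split.
#
# An 80/20 train/test split illustrates each PRS at full resolution:
# clumping+thresholding on logistic betas, L1-penalised summary-statistic
# regression, and the infinitesimal-prior closed form. LD references and
# imputation means come from the training side only. Writes model weights
# and test AUCs.

library(prsfs)

ds <- read_dataset(file.path("results", "qc"))
gt <- ds$genotypes; ph <- ds$phenotypes
out_dir <- file.path("results", "prs")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

set.seed(20260105)
tr <- prsfs:::stratified_split(ph$status, 0.8, 20260105)
gt_tr <- gt_subset(gt, samples = which(tr))
gt_te <- gt_subset(gt, samples = which(!tr))
y_tr <- ph$status[tr]; y_te <- ph$status[!tr]
g_means <- colMeans(gt_tr$dosages, na.rm = TRUE)

pca <- genotype_pca(gt_tr, n_pcs = 10, seed = 1)
covars <- ph[, c("age", "sex", "bmi", "ldl", "hdl", "trig", "sbp",
                 "smoking", "diabetes")]
stats <- logistic_gwas(gt_tr, y_tr, covariates = covars[tr, ],
                       pcs = pca$scores)
blocks <- build_ld_blocks(gt_tr, max_block_variants = 100)
rmarg <- marginal_correlations(gt_tr, y_tr)

models <- list(
  pt = pt_fit(stats, gt_tr, y_tr, fold = 0, seed = 2),
  lassosum = lassosum_fit(rmarg, blocks, genotypes_train = gt_tr,
                          status_train = y_tr, fold = 0, seed = 3),
  inf = inf_fit(rmarg, blocks, h2 = 0.5, N = sum(tr), fold = 0,
                train_ids = rownames(gt_tr$dosages)))

for (nm in names(models)) {
  mo <- models[[nm]]
  sc <- prs_score(gt_te, mo, means = g_means)
  cat(sprintf("%-8s %4d variants, test AUC %.3f, hyper: %s\n",
              nm, length(mo$ids), auc(sc, y_te),
              paste(names(mo$hyper), unlist(mo$hyper), sep = "=",
                    collapse = " ")))
  write.table(data.frame(ID = mo$ids, WEIGHT = mo$weights),
              file.path(out_dir, paste0(nm, "_weights.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(method = mo$method, fold = mo$fold),
                         mo$hyper),
                       file.path(out_dir, paste0(nm, "_meta.json")),
                       auto_unbox = TRUE)
}
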