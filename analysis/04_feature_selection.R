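#!/usr/bin/env Rscript
# Stage 4: the three SNP-selection strategies on the full QC'd cohort.
#
# Univariate (Fisher-scan) ranking, greedy mRMR, and random-forest impurity
# importance, each truncated at the top-k grid. This stage is illustrative
# (whole-cohort rankings); the leakage-free per-fold selections happen in
# stage 6. Writes a tidy ranking table.

library(prsfs)

ds <- read_dataset(file.path("results", "qc"))
gt <- ds$genotypes; ph <- ds$phenotypes
out_dir <- file.path("results", "feature_selection")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

stats_fis <- read.delim(file.path("results", "gwas", "fisher_scan.tsv"))
st <- structure(data.frame(id = stats_fis$ID, chrom = stats_fis$CHR,
                           pos = stats_fis$POS, beta = stats_fis$BETA,
                           se = stats_fis$SE, p = stats_fis$P,
                           af_case = stats_fis$AF_CASE,
                           af_ctrl = stats_fis$AF_CTRL,
                           converged = stats_fis$CONVERGED),
                class = c("summary_stats", "data.frame"))

rankings <- list(
  gwas = rank_by_gwas(st),
  mrmr = mrmr_select(gt, ph$status, k = min(100, ncol(gt$dosages))),
  rf = rf_importance_rank(gt, ph$status, fs_config(seed = 20260104)))

tidy <- do.call(rbind, lapply(rankings, function(rk)
  data.frame(METHOD = rk$method, RANK = rk$rank, ID = rk$id,
             SCORE = rk$score)))
write.table(tidy, file.path(out_dir, "rankings.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path("results", "cohort", "truth.json"),
                             simplifyVector = TRUE)
ids_all <- sprintf("snp%05d", seq_along(truth$block_ids))
causal_blocks <- truth$block_ids[match(truth$causal_ids, ids_all)]
for (nm in names(rankings)) {
  top50 <- select_top_k(rankings[[nm]], min(50, nrow(rankings[[nm]])))
  top_blocks <- truth$block_ids[match(top50, ids_all)]
  cat(sprintf("%-5s top-50 recovers %d of %d causal LD blocks (%d exact)\n",
              nm, sum(causal_blocks %in% top_blocks),
              length(causal_blocks), sum(top50 %in% truth$causal_ids)))
}
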