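#!/usr/bin/env Rscript
# Stage 1: generate the synthetic case/control cohort.
#
# The generator emulates the statistical structure the downstream protocol
# assumes: biallelic SNPs in LD blocks, two mildly diverged subpopulations,
# a liability-threshold phenotype driven by 20 planted causal variants
# (h2 = 0.5, prevalence 0.3), correlated clinical risk factors, 2% missing
# calls, and three planted duplicate-sample pairs for the kinship filter.
# Outputs a VCF + TSV + ground-truth JSON under results/cohort/.

library(prsfs)

out_dir <- file.path("results", "cohort")
cfg <- sim_config(n_samples = 1500, n_variants = 1500, n_blocks = 75,
                  within_block_corr = 0.8, maf_range = c(0.05, 0.5),
                  n_subpops = 2, fst = 0.02, n_causal = 20,
                  h2_liability = 0.5, prevalence = 0.3,
                  missing_rate = 0.02, n_duplicate_pairs = 3,
                  bp_per_block = 100000, seed = 20260101)

coh <- simulate_cohort(cfg)
write_dataset(coh$genotypes, coh$phenotypes, out_dir, truth = coh$truth)
jsonlite::write_json(coh$pairs, file.path(out_dir, "planted_pairs.json"))

cat(sprintf("cohort: %d samples x %d variants, %.1f%% cases, %.2f%% missing\n",
            nrow(coh$genotypes$dosages), ncol(coh$genotypes$dosages),
            100 * mean(coh$phenotypes$status),
            100 * mean(is.na(coh$genotypes$dosages))))
cat(sprintf("planted: %d causal variants, %d duplicate pairs\n",
            length(coh$truth$causal_ids), nrow(coh$pairs)))
cat("written to", out_dir, "\n")
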