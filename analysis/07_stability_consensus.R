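#!/usr/bin/env Rscript
# Stage 7: feature-selection stability and cross-method consensus.
#
# From the per-fold selections of stage 6: pairwise top-k overlap per
# method, per-variant selection frequency, the stable sets (selected in at
# least 5 of 10 folds), the cross-method consensus, and a ground-truth
# audit of the consensus against the planted causal blocks.

library(prsfs)

sel <- read.delim(file.path("results", "cv", "selections.tsv"))
out_dir <- file.path("results", "stability")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

rows <- list()
for (fm in unique(sel$METHOD)) for (k in unique(sel$K)) {
  sets <- lapply(split(sel$ID[sel$METHOD == fm & sel$K == k],
                       sel$FOLD[sel$METHOD == fm & sel$K == k]), identity)
  if (length(sets) < 2) next
  rows[[length(rows) + 1]] <-
    data.frame(METHOD = fm, K = k,
               OVERLAP_PCT = overlap_percentage(sets, k))
}
stab <- do.call(rbind, rows)
write.table(stab, file.path(out_dir, "overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("top-k overlap percentage across folds:\n")
print(stab, row.names = FALSE, digits = 3)

k_stab <- max(sel$K)
stable_sets <- list()
for (fm in unique(sel$METHOD)) {
  sets <- split(sel$ID[sel$METHOD == fm & sel$K == k_stab],
                sel$FOLD[sel$METHOD == fm & sel$K == k_stab])
  fr <- selection_frequency(sets, threshold = 5)
  stable_sets[[fm]] <- fr$stable
  write.table(data.frame(ID = names(fr$counts), COUNT = fr$counts),
              file.path(out_dir, paste0("frequency_", fm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-5s: %d variants stable (>= 5 of 10 folds) at k = %d\n",
              fm, length(fr$stable), k_stab))
}
consensus <- consensus_variants(stable_sets)
writeLines(consensus, file.path(out_dir, "consensus_variants.txt"))
cat(sprintf("consensus across all methods: %d variants\n",
            length(consensus)))

truth <- jsonlite::read_json(file.path("results", "cohort", "truth.json"),
                             simplifyVector = TRUE)
ids_all <- sprintf("snp%05d", seq_along(truth$block_ids))
causal_blocks <- truth$block_ids[match(truth$causal_ids, ids_all)]
proxy <- ids_all[truth$block_ids %in% causal_blocks]
cat(sprintf("consensus variants inside causal LD blocks: %d of %d\n",
            sum(consensus %in% proxy), length(consensus)))
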