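test_that("minor allele frequency folds correctly", {
  expect_equal(compute_maf(rep(1, 10)), 0.5)
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)
  expect_equal(compute_maf(c(2, 2, 1, 0, NA)), 0.375)  # alt 5/8 folded
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("HWE exact test matches full enumeration", {
  expect_equal(hwe_exact_test(7, 0, 0), 1.0)
  expect_equal(hwe_exact_test(1, 0, 1), hwe_oracle(1, 0, 1),
               tolerance = 1e-12)
  expect_equal(hwe_exact_test(3, 4, 3), hwe_oracle(3, 4, 3),
               tolerance = 1e-12)
  # every genotype table with total <= 12, plus seeded larger ones up to 200
  for (N in 1:12) for (aa in 0:N) for (ab in 0:(N - aa)) {
    bb <- N - aa - ab
    expect_equal(hwe_exact_test(aa, ab, bb), hwe_oracle(aa, ab, bb),
                 tolerance = 1e-12,
                 label = sprintf("hwe(%d,%d,%d)", aa, ab, bb))
  }
  set.seed(31)
  for (rep in 1:25) {
    cnt <- as.vector(rmultinom(1, sample(20:200, 1), runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("variant filter chain removes the right markers in order", {
  thr <- qc_thresholds(maf_min = 0.05, variant_missing_max = 0.2,
                       mac_min = 3, hwe_p_min = 0.01)
  n <- 40
  set.seed(41)
  clean <- function() rbinom(n, 2, 0.4)
  d <- cbind(
    v_missing = c(rep(NA, 15), clean()[16:n]),     # 37.5% missing
    v_rare    = c(1, rep(0, n - 1)),               # MAF 1/80
    v_mac     = c(1, 1, rep(0, n - 2)),            # MAF 0.025 < 0.05 too...
    v_hwe     = rep(c(0, 2), n / 2),               # no hets: HWE blown
    v_ok1     = clean(),
    v_ok2     = clean())
  # make v_mac pass MAF but fail MAC: MAF 0.05 needs 4 alleles of 80 = MAC 4
  # with mac_min 5
  thr <- qc_thresholds(maf_min = 0.04, variant_missing_max = 0.2,
                       mac_min = 5, hwe_p_min = 0.01)
  d[, "v_rare"] <- c(1, rep(0, n - 1))             # MAF 0.0125 < 0.04
  d[, "v_mac"] <- c(1, 1, 1, 1, rep(0, n - 4))     # MAF 0.05, MAC 4 < 5
  gt <- make_gt(d)
  res <- filter_variants(gt, thr)
  expect_equal(unname(res$report$removed_counts),
               c(1L, 1L, 1L, 1L))
  expect_equal(res$report$n_retained, 2)
  expect_identical(res$genotypes$variant_info$id,
                   gt$variant_info$id[5:6])
  # idempotence
  res2 <- filter_variants(res$genotypes, thr)
  expect_identical(res2$genotypes$dosages, res$genotypes$dosages)
  expect_equal(sum(res2$report$removed_counts), 0)
})

test_that("clean matrices pass the variant filters untouched", {
  set.seed(42)
  d <- matrix(rbinom(500 * 20, 2, 0.25), 500, 20)
  res <- filter_variants(make_gt(d), qc_thresholds(mac_min = 10))
  expect_equal(res$report$n_retained, 20)
})

test_that("sample filter removes only samples above the threshold", {
  set.seed(43)
  d <- matrix(rbinom(10 * 20, 2, 0.3), 10, 20)
  d[1, 1:10] <- NA           # 50% missing -> removed
  d[2, 1:4] <- NA            # exactly 20% -> retained (strict inequality)
  gt <- make_gt(d)
  res <- filter_samples(gt, qc_thresholds(sample_missing_max = 0.2))
  expect_equal(res$report$n_retained, 9)
  expect_identical(res$report$removed$missingness,
                   rownames(gt$dosages)[1])
  res2 <- filter_samples(res$genotypes, qc_thresholds())
  expect_identical(res2$genotypes$dosages, res$genotypes$dosages)
})

test_that("ld_r2 equals squared Pearson correlation", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1.0)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1.0)
  x <- c(0, 0, 1, 2); y <- c(0, 1, 1, 2)
  expect_equal(ld_r2(x, y), cor(x, y)^2)
  expect_equal(ld_r2(x, y),
               (sum((x - mean(x)) * (y - mean(y))))^2 /
                 (sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_true(is.na(ld_r2(c(1, 1, 1, 1), c(0, 1, 2, 0))))
  expect_true(is.na(ld_r2(c(NA, NA, 1, NA), c(0, 1, 2, 0))))
})

test_that("ld_prune keeps the higher-MAF member of a duplicate pair", {
  set.seed(44)
  base <- rbinom(100, 2, 0.3)
  other <- rbinom(100, 2, 0.45)
  d <- cbind(base, base, other)
  gt <- make_gt(d, pos = c(1000, 2000, 400000))
  kept <- ld_prune(gt, qc_thresholds(ld_r2_max = 0.1,
                                     ld_window_bp = 500000,
                                     ld_step_variants = 1))
  expect_equal(sum(kept %in% c("v001", "v002")), 1)
  expect_true("v001" %in% kept)  # equal MAF -> later position dropped
  expect_true("v003" %in% kept)
})

test_that("uncorrelated variants all survive pruning", {
  set.seed(45)
  d <- matrix(rbinom(400 * 15, 2, 0.3), 400, 15)
  gt <- make_gt(d)
  kept <- ld_prune(gt, qc_thresholds(ld_r2_max = 0.3))
  expect_equal(length(kept), 15)
})

test_that("pruning guarantee verified by exhaustive pairwise check", {
  cfg <- sim_config(n_samples = 500, n_variants = 60, n_blocks = 3,
                    within_block_corr = 0.9, missing_rate = 0.02,
                    bp_per_block = 50000, seed = 46)
  gt <- simulate_genotypes(cfg)$genotypes
  thr <- qc_thresholds(ld_r2_max = 0.1, ld_window_bp = 100000,
                       ld_step_variants = 5)
  kept <- ld_prune(gt, thr)
  expect_gt(length(kept), 0)
  idx <- match(kept, gt$variant_info$id)
  pos <- gt$variant_info$pos[idx]
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (b <= a) next
    if (abs(pos[b] - pos[a]) > thr$ld_window_bp) next
    r2 <- ld_r2(gt$dosages[, idx[a]], gt$dosages[, idx[b]])
    expect_false(!is.na(r2) && r2 > thr$ld_r2_max,
                 label = sprintf("retained pair %s-%s r2=%.3f",
                                 kept[a], kept[b], r2))
  }
})

test_that("KING kinship behaves on duplicates, opposites, unrelateds", {
  set.seed(47)
  x <- rbinom(200, 2, 0.4)
  expect_equal(king_kinship(x, x), 0.5)
  expect_true(is.na(king_kinship(rep(0, 100), rep(2, 100))))
  expect_error(king_kinship(x[1:10], x[1:10]), "shared")
  a <- rbinom(5000, 2, runif(5000, 0.1, 0.5))
  b <- rbinom(5000, 2, runif(5000, 0.1, 0.5))
  p <- runif(5000, 0.1, 0.5)
  a <- rbinom(5000, 2, p); b <- rbinom(5000, 2, p)
  expect_lt(abs(king_kinship(a, b)), 0.044)
})

test_that("kinship matrix agrees with the pairwise estimator", {
  cfg <- sim_config(n_samples = 20, n_variants = 300, n_blocks = 10,
                    missing_rate = 0.05, seed = 48)
  gt <- simulate_genotypes(cfg)$genotypes
  phi <- kinship_matrix(gt, min_overlap = 50)
  for (i in c(1, 5, 12)) for (j in c(3, 9, 20)) {
    expect_equal(phi[i, j], king_kinship(gt$dosages[i, ], gt$dosages[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("greedy relatedness removal clears all flagged pairs", {
  cfg <- sim_config(n_samples = 60, n_variants = 2000, n_blocks = 50,
                    missing_rate = 0, seed = 49)
  gt <- simulate_genotypes(cfg)$genotypes
  res0 <- remove_related(gt, kinship_max = 0.177)
  expect_equal(length(res0$removed), 0)
  # one planted duplicate pair -> exactly one member removed
  sr <- spike_relatedness(gt, 1, seed = 2)
  res1 <- remove_related(sr$genotypes, kinship_max = 0.177)
  expect_equal(length(res1$removed), 1)
  expect_true(res1$removed %in% unlist(sr$pairs[1, ]))
  # a 3-clique of duplicates -> 2 removed, earliest member retained
  d <- gt$dosages
  tri <- rbind(d, d[1, , drop = FALSE], d[1, , drop = FALSE])
  rownames(tri) <- c(rownames(d), "dupA", "dupB")
  gt3 <- genotype_matrix(tri, gt$variant_info)
  res3 <- remove_related(gt3, kinship_max = 0.177)
  expect_setequal(res3$removed, c("dupA", "dupB"))
  # invariant: no retained pair above threshold
  phi <- kinship_matrix(gt_subset(gt3, samples = res3$retained))
  expect_true(all(phi[upper.tri(phi)] <= 0.177, na.rm = TRUE))
})
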