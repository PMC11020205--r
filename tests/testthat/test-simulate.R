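test_that("simulation is deterministic under its seed", {
  cfg <- sim_config(n_samples = 200, n_variants = 100, n_blocks = 10,
                    seed = 11, missing_rate = 0.05, n_duplicate_pairs = 2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$causal_betas, b$truth$causal_betas)
  c2 <- simulate_cohort(sim_config(n_samples = 200, n_variants = 100,
                                   n_blocks = 10, seed = 12))
  expect_false(identical(a$genotypes$dosages[1:50, ],
                         c2$genotypes$dosages[1:50, ]))
})

test_that("no divergence and no LD when fst = 0 and corr = 0", {
  cfg <- sim_config(n_samples = 1000, n_variants = 400, n_blocks = 20,
                    within_block_corr = 0, fst = 0, n_subpops = 2,
                    missing_rate = 0, seed = 5)
  sim <- simulate_genotypes(cfg)
  d <- sim$genotypes$dosages
  sp <- sim$truth$subpop_labels
  p1 <- colMeans(d[sp == 1, ]) / 2
  p2 <- colMeans(d[sp == 2, ]) / 2
  p <- colMeans(d) / 2
  se <- sqrt(p * (1 - p) * (1 / sum(sp == 1) + 1 / sum(sp == 2)) / 2)
  expect_lt(mean(abs(p1 - p2)), 3 * mean(se))
  r2_adj <- vapply(seq_len(ncol(d) - 1), function(j)
    ld_r2(d[, j], d[, j + 1]), 0)
  blocks <- rep(seq_len(20), each = 20)
  same_block <- blocks[-length(blocks)] == blocks[-1]
  expect_lt(mean(r2_adj[same_block], na.rm = TRUE),
            1 / nrow(d) + 3 * sqrt(2) / nrow(d))
})

test_that("within-block LD is present and absent across blocks", {
  cfg <- sim_config(n_samples = 1500, n_variants = 300, n_blocks = 15,
                    within_block_corr = 0.8, fst = 0, missing_rate = 0,
                    seed = 6)
  sim <- simulate_genotypes(cfg)
  d <- sim$genotypes$dosages
  blocks <- sim$truth$block_ids
  r2_adj <- vapply(seq_len(ncol(d) - 1), function(j)
    ld_r2(d[, j], d[, j + 1]), 0)
  same <- blocks[-length(blocks)] == blocks[-1]
  expect_gt(mean(r2_adj[same], na.rm = TRUE), 0.2)
  expect_lt(mean(r2_adj[!same], na.rm = TRUE), 0.05)
})

test_that("Hudson FST over variants recovers the configured divergence", {
  cfg <- sim_config(n_samples = 2000, n_variants = 2000, n_blocks = 100,
                    fst = 0.1, n_subpops = 2, missing_rate = 0, seed = 7)
  sim <- simulate_genotypes(cfg)
  fst_hat <- hudson_fst(sim$genotypes$dosages, sim$truth$subpop_labels)
  expect_lt(abs(fst_hat - 0.1), 0.02)
})

test_that("sample MAF tracks the generative frequencies", {
  cfg <- sim_config(n_samples = 1500, n_variants = 300, n_blocks = 15,
                    fst = 0, missing_rate = 0, seed = 8)
  sim <- simulate_genotypes(cfg)
  p_hat <- colMeans(sim$genotypes$dosages) / 2
  p_gen <- sim$truth$ancestral_freqs
  se <- sqrt(p_gen * (1 - p_gen) / (2 * nrow(sim$genotypes$dosages)))
  expect_true(all(abs(p_hat - p_gen) <= 4 * se))
})

null_covariate_spec <- function() {
  sp <- default_covariate_spec()
  lapply(sp, function(s) { s$beta <- 0; s })
}

test_that("case fraction matches prevalence on pure noise", {
  cfg <- sim_config(n_samples = 4000, n_variants = 50, n_blocks = 5,
                    n_causal = 0, h2_liability = 0, prevalence = 0.3,
                    covariate_spec = null_covariate_spec(),
                    missing_rate = 0, seed = 9)
  coh <- simulate_cohort(cfg)
  frac <- mean(coh$phenotypes$status)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
})

test_that("true liability is a strong classifier of status", {
  cfg <- sim_config(n_samples = 4000, n_variants = 1000, n_blocks = 50,
                    n_causal = 20, h2_liability = 0.5, prevalence = 0.3,
                    missing_rate = 0, seed = 10)
  coh <- simulate_cohort(cfg)
  expect_gte(auc(coh$truth$liability, coh$phenotypes$status), 0.75)
  g <- scale(coh$genotypes$dosages[, match(coh$truth$causal_ids,
                                           coh$genotypes$variant_info$id)])
  gl <- drop(g %*% coh$truth$causal_betas)
  expect_equal(var(gl), 0.5, tolerance = 1e-6)
})

test_that("risk factors honour their marginals and liability effects", {
  cfg <- sim_config(n_samples = 10000, seed = 13)
  rf <- simulate_risk_factors(cfg)
  expect_lt(abs(mean(rf$sex) - 0.456), 3 * sqrt(0.456 * 0.544 / 10000))
  expect_lt(abs(mean(rf$age) - 56.5), 3 * 8.1 / sqrt(10000))
  # negative HDL effect recovered by a single-covariate logistic refit
  cfg2 <- sim_config(n_samples = 5000, n_variants = 50, n_blocks = 5,
                     n_causal = 0, h2_liability = 0, seed = 14,
                     missing_rate = 0)
  coh <- simulate_cohort(cfg2)
  fit <- glm(status ~ hdl, data = coh$phenotypes, family = binomial())
  expect_lt(coef(fit)["hdl"], 0)
})

test_that("zero-effect covariates are independent of status", {
  cfg <- sim_config(n_samples = 4000, n_variants = 50, n_blocks = 5,
                    n_causal = 0, h2_liability = 0,
                    covariate_spec = null_covariate_spec(),
                    missing_rate = 0, seed = 15)
  coh <- simulate_cohort(cfg)
  for (nm in c("age", "bmi", "hdl", "smoking"))
    expect_lte(abs(cor(coh$phenotypes[[nm]], coh$phenotypes$status)),
               3 / sqrt(4000))
})

test_that("missingness injection hits the requested rate", {
  cfg <- sim_config(n_samples = 1000, n_variants = 100, n_blocks = 10,
                    missing_rate = 0, seed = 16)
  gt <- simulate_genotypes(cfg)$genotypes
  expect_identical(inject_missingness(gt, 0, seed = 1)$dosages, gt$dosages)
  g2 <- inject_missingness(gt, 0.5, seed = 2)
  fr <- mean(is.na(g2$dosages))
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / (1000 * 100)))
  g3 <- inject_missingness(gt, 0.25, seed = 3, variants = "snp00007")
  cr <- mean(!is.na(g3$dosages[, "snp00007"]))
  expect_lt(abs(cr - 0.75), 4 * sqrt(0.25 * 0.75 / 1000))
  expect_identical(g3$dosages[, -7], gt$dosages[, -7])
})

test_that("duplicate spiking plants exact copies with kinship 0.5", {
  cfg <- sim_config(n_samples = 200, n_variants = 200, n_blocks = 10,
                    missing_rate = 0, seed = 17)
  gt <- simulate_genotypes(cfg)$genotypes
  expect_identical(spike_relatedness(gt, 0, seed = 1)$genotypes$dosages,
                   gt$dosages)
  sr <- spike_relatedness(gt, 5, seed = 1)
  expect_equal(nrow(sr$genotypes$dosages), 205)
  expect_equal(nrow(sr$pairs), 5)
  for (i in seq_len(5)) {
    x <- sr$genotypes$dosages[sr$pairs$source[i], ]
    y <- sr$genotypes$dosages[sr$pairs$duplicate[i], ]
    expect_identical(x, setNames(y, names(x)))
    expect_equal(king_kinship(x, y), 0.5)
  }
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(maf_range = c(0, 0.5)))
  expect_error(sim_config(n_variants = 10, n_blocks = 20, n_causal = 0),
               "block")
  expect_error(sim_config(n_causal = 50, n_variants = 20))
  cfg <- sim_config(n_samples = 100, n_variants = 20, n_blocks = 2,
                    h2_liability = 0.9, seed = 1)
  sg <- simulate_genotypes(cfg)
  rf <- simulate_risk_factors(cfg)
  expect_error(simulate_phenotype(sg$genotypes, sg$truth, rf, cfg),
               "budget")
})
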