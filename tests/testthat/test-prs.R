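fake_stats <- function(ids, p, beta = NULL, pos = NULL, chrom = "1") {
  if (is.null(beta)) beta <- rep(0.1, length(ids))
  if (is.null(pos)) pos <- seq_along(ids) * 1000L
  structure(data.frame(id = ids, chrom = chrom, pos = pos, beta = beta,
                       se = 0.1, p = p, af_case = 0.3, af_ctrl = 0.3,
                       converged = TRUE, stringsAsFactors = FALSE),
            class = c("summary_stats", "data.frame"))
}

test_that("clumping keeps independent variants and drops LD partners", {
  set.seed(81)
  n <- 300
  d <- matrix(rbinom(n * 6, 2, 0.35), n, 6)
  gt <- make_gt(d)
  st <- fake_stats(gt$variant_info$id, p = runif(6), pos = gt$variant_info$pos)
  expect_setequal(clump(st, gt), gt$variant_info$id)

  dup <- cbind(d[, 1], d[, 1], d[, 3:6])
  gtd <- make_gt(dup)
  st2 <- fake_stats(gtd$variant_info$id, p = c(1e-8, 1e-4, runif(4)),
                    pos = gtd$variant_info$pos)
  idx <- clump(st2, gtd)
  expect_true("v001" %in% idx)
  expect_false("v002" %in% idx)
})

test_that("clumping equals the hand-simulated greedy pass on 15 variants", {
  cfg <- sim_config(n_samples = 400, n_variants = 15, n_blocks = 3,
                    n_causal = 0, within_block_corr = 0.9,
                    bp_per_block = 3000, missing_rate = 0, seed = 82)
  gt <- simulate_genotypes(cfg)$genotypes
  set.seed(83)
  st <- fake_stats(gt$variant_info$id, p = runif(15),
                   pos = gt$variant_info$pos)
  got <- clump(st, gt, r2_max = 0.2, window_bp = 2000)
  want <- clump_oracle(st, gt, r2_max = 0.2, window_bp = 2000)
  expect_identical(got, want)
})

test_that("P+T returns null-level inner AUC on null data and obeys ties", {
  set.seed(84)
  n <- 2000
  d <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
  y <- rbinom(n, 1, 0.5)
  gt <- make_gt(d)
  st <- logistic_gwas(gt, y)
  mod <- pt_fit(st, gt, y, fold = 1, seed = 5)
  expect_lte(mod$hyper$inner_auc, 0.55)
  expect_identical(mod$fold, 1)

  # one dominant SNP: every threshold admitting it ties, smallest wins
  set.seed(85)
  g <- rbinom(n, 2, 0.4)
  y2 <- as.integer(runif(n) < plogis(-1 + 1.5 * g))
  d2 <- cbind(g, matrix(rbinom(n * 5, 2, 0.3), n, 5))
  gt2 <- make_gt(d2)
  st2 <- logistic_gwas(gt2, y2)
  mod2 <- pt_fit(st2, gt2, y2, seed = 6)
  thr_grid <- sort(c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1))
  first_admitting <- thr_grid[thr_grid >= min(st2$p)][1]
  if (mod2$hyper$threshold > first_admitting)
    expect_gt(length(mod2$ids), 1)  # a later threshold won outright
  expect_true("v001" %in% mod2$ids)
})

test_that("P+T on planted signal retains causal-or-proxy variants", {
  cfg <- sim_config(n_samples = 1500, n_variants = 1000, n_blocks = 50,
                    n_causal = 20, h2_liability = 0.5, prevalence = 0.3,
                    missing_rate = 0, fst = 0, seed = 86)
  coh <- simulate_cohort(cfg)
  st <- logistic_gwas(coh$genotypes, coh$phenotypes$status)
  mod <- pt_fit(st, coh$genotypes, coh$phenotypes$status, seed = 7)
  prox <- proxy_set(coh$truth, coh$genotypes$variant_info)
  expect_gte(sum(mod$ids %in% prox), 10)
})

test_that("polygenic scores are exact weighted dosage sums", {
  gt <- make_gt(rbind(c(0, 1, 2), c(2, NA, 0)))
  m0 <- prsfs:::new_prs_model("pt", gt$variant_info$id, c(0, 0, 0),
                              list(), 1, NULL)
  expect_equal(as.numeric(prs_score(gt, m0)), c(0, 0))
  m1 <- prsfs:::new_prs_model("pt", "v002", 1, list(), 1, NULL)
  expect_equal(as.numeric(prs_score(gt, m1, means = c(v002 = 1))), c(1, 1))
  m2 <- prsfs:::new_prs_model("pt", gt$variant_info$id, c(0.5, -1, 2),
                              list(), 1, NULL)
  sc <- prs_score(gt, m2)
  expect_equal(as.numeric(sc), c(0.5 * 0 - 1 * 1 + 2 * 2,
                             0.5 * 2 - 1 * 1 + 2 * 0))
  m3 <- prsfs:::new_prs_model("pt", c("v001", "absent"), c(1, 5),
                              list(), 1, NULL)
  sc3 <- prs_score(gt, m3)
  expect_equal(attr(sc3, "n_absent"), 1L)
  expect_equal(as.numeric(sc3), c(0, 2))
})

test_that("lassosum reduces to soft-thresholding at s = 1", {
  set.seed(87)
  m <- 12
  R <- diag(m)  # ignored at s = 1
  r <- runif(m, -0.5, 0.5)
  blocks <- list(list(ids = sprintf("v%03d", 1:m), R = R, sd = rep(1, m)))
  names(r) <- blocks[[1]]$ids
  mod <- lassosum_fit(r, blocks, lambda_grid = 0.1, s_grid = 1)
  expect_equal(unname(mod$weights),
               unname(sign(r) * pmax(abs(r) - 0.1, 0)), tolerance = 1e-10)
  mod0 <- lassosum_fit(r, blocks, lambda_grid = max(abs(r)) + 0.01,
                       s_grid = 1)
  expect_true(all(mod0$weights == 0))
})

test_that("lassosum matches an independent convex-optimization oracle", {
  set.seed(88)
  m <- 10
  X <- matrix(rnorm(200 * m), 200, m)
  R <- cor(X)
  r <- runif(m, -0.4, 0.4)
  ids <- sprintf("v%03d", 1:m)
  names(r) <- ids
  blocks <- list(list(ids = ids, R = R, sd = rep(1, m)))
  for (prm in list(c(0.05, 0.5), c(0.02, 0.9), c(0.1, 0.2))) {
    lam <- prm[1]; s <- prm[2]
    mod <- lassosum_fit(r, blocks, lambda_grid = lam, s_grid = s)
    beta_cd <- unname(mod$weights)
    beta_or <- unname(lassosum_glmnet_oracle(R, r, lam, s))
    f_cd <- lassosum_objective(beta_cd, R, r, lam, s)
    f_or <- lassosum_objective(beta_or, R, r, lam, s)
    expect_equal(f_cd, f_or, tolerance = 1e-6)
    expect_equal(beta_cd, beta_or, tolerance = 1e-4)
  }
})

test_that("lassosum L1 norm is monotone along the penalty path", {
  set.seed(89)
  m <- 15
  X <- matrix(rnorm(300 * m), 300, m)
  R <- cor(X)
  r <- runif(m, -0.4, 0.4)
  ids <- sprintf("v%03d", 1:m)
  names(r) <- ids
  blocks <- list(list(ids = ids, R = R, sd = rep(1, m)))
  for (s in c(0.5, 1)) {
    norms <- vapply(c(0.01, 0.05, 0.1, 0.2), function(lam) {
      sum(abs(lassosum_fit(r, blocks, lambda_grid = lam,
                           s_grid = s)$weights))
    }, 0)
    expect_true(all(diff(norms) <= 1e-10))
  }
})

test_that("infinitesimal shrinkage has the exact closed forms", {
  m <- 8
  r <- seq(-0.3, 0.4, length.out = m)
  ids <- sprintf("v%03d", 1:m)
  names(r) <- ids
  blocks <- list(list(ids = ids, R = diag(m), sd = rep(1, m)))
  mod <- inf_fit(r, blocks, h2 = 0.5, M = m, N = 100)
  expect_equal(unname(mod$weights), unname(r) / (1 + m / (100 * 0.5)),
               tolerance = 1e-10)
  mod_big <- inf_fit(r, blocks, h2 = 1, M = m, N = 1e9)
  expect_equal(unname(mod_big$weights), unname(r), tolerance = 1e-6)

  set.seed(90)
  X <- matrix(rnorm(400 * 5), 400, 5)
  R5 <- cor(X)
  r5 <- runif(5, -0.3, 0.3)
  ids5 <- sprintf("w%03d", 1:5)
  names(r5) <- ids5
  b5 <- list(list(ids = ids5, R = R5, sd = rep(1, 5)))
  mod5 <- inf_fit(r5, b5, h2 = 0.3, M = 5, N = 250)
  A <- R5 + diag(5 / (250 * 0.3), 5)
  ev <- eigen(A, symmetric = TRUE)  # independent dense-solve route
  beta_or <- ev$vectors %*% ((t(ev$vectors) %*% r5) / ev$values)
  expect_equal(unname(mod5$weights), drop(beta_or), tolerance = 1e-10)
})
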