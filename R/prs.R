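#' Greedy p-value clumping
#'
#' Iterates variants by ascending p; each not-yet-removed variant becomes an
#' index and removes all unprocessed variants within `window_bp` whose r^2
#' with it exceeds `r2_max`, using the reference genotypes for LD.
#'
#' @param stats `summary_stats` for the candidate variants.
#' @param genotypes_ref [genotype_matrix()] supplying reference LD
#'   (training fold).
#' @param r2_max clumping r^2 threshold.
#' @param window_bp clumping window.
#' @return character vector of index variant ids (ascending p).
#' @export
clump <- function(stats, genotypes_ref, r2_max = 0.1, window_bp = 250000) {
  ids <- genotypes_ref$variant_info$id
  j <- match(stats$id, ids)
  if (anyNA(j)) stop("stats and reference genotypes share no alignment")
  o <- order(stats$p, stats$id)
  removed <- rep(FALSE, nrow(stats))
  index <- logical(nrow(stats))
  pos <- stats$pos; chrom <- stats$chrom
  d <- genotypes_ref$dosages
  for (ii in o) {
    if (removed[ii]) next
    index[ii] <- TRUE
    near <- which(!removed & !index & chrom == chrom[ii] &
                  abs(pos - pos[ii]) <= window_bp)
    if (length(near)) {
      r2 <- ld_r2_one_to_many(d[, j[ii]], d[, j[near], drop = FALSE])
      removed[near[!is.na(r2) & r2 > r2_max]] <- TRUE
    }
  }
  stats$id[index][order(stats$p[index], stats$id[index])]
}

new_prs_model <- function(method, ids, weights, hyper, fold, train_ids,
                          scale = "dosage") {
  stopifnot(length(ids) == length(weights), all(is.finite(weights)),
            !anyDuplicated(ids))
  structure(list(method = method, ids = ids, weights = weights,
                 hyper = hyper, fold = fold, train_ids = train_ids,
                 scale = scale),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("prs_model [%s]: %d variants, fold %s\n",
              x$method, length(x$ids), as.character(x$fold)))
  invisible(x)
}

stratified_split <- function(status, frac, seed) {
  with_seed(seed, {
    tr <- logical(length(status))
    for (s in unique(status)) {
      idx <- which(status == s)
      n_tr <- max(1, round(frac * length(idx)))
      tr[sample(idx, n_tr)] <- TRUE
    }
    tr
  })
}

#' Clumping + thresholding polygenic score
#'
#' For each p-value threshold, the panel is the clumped index variants with
#' `p <= threshold` and weights are their log-odds betas; the threshold
#' maximizing AUC on a seeded inner 80/20 split of the training fold is
#' chosen (ties toward the smaller threshold).
#'
#' @param stats training-fold `summary_stats` (logistic scan).
#' @param genotypes_train training-fold [genotype_matrix()].
#' @param status_train training-fold phenotype.
#' @param thresholds p-value grid.
#' @param r2_max,window_bp clumping parameters.
#' @param fold fold id recorded for the leakage contract.
#' @param seed inner-split seed.
#' @return a `prs_model`.
#' @export
pt_fit <- function(stats, genotypes_train, status_train,
                   thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                  0.1, 0.5, 1),
                   r2_max = 0.1, window_bp = 250000, fold = NA, seed = 1) {
  idx_ids <- clump(stats, genotypes_train, r2_max, window_bp)
  st <- stats[match(idx_ids, stats$id), , drop = FALSE]
  st <- st[st$converged & !is.na(st$beta), , drop = FALSE]
  inner <- stratified_split(status_train, 0.8, seed)
  means <- colMeans(genotypes_train$dosages[inner, , drop = FALSE],
                    na.rm = TRUE)
  best <- NULL
  for (thr in sort(thresholds)) {
    panel <- st[st$p <= thr, , drop = FALSE]
    if (nrow(panel) == 0) next
    mod <- new_prs_model("pt", panel$id, panel$beta,
                         list(threshold = thr), fold, NULL)
    sc <- prs_score(gt_subset(genotypes_train, samples = which(!inner)),
                    mod, means = means)
    a <- auc(sc, status_train[!inner])
    if (is.null(best) || a > best$auc + 1e-12)
      best <- list(auc = a, thr = thr, panel = panel)
  }
  if (is.null(best)) stop("no threshold yields a non-empty panel")
  new_prs_model("pt", best$panel$id, best$panel$beta,
                list(threshold = best$thr, inner_auc = best$auc),
                fold, rownames(genotypes_train$dosages))
}

#' Score samples with a polygenic-score model
#'
#' `score_i = sum_j w_j dosage_ij`; missing dosages are mean-imputed per
#' variant (training means when supplied). Model variants absent from the
#' matrix contribute 0 and are counted in attribute `n_absent`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param model a `prs_model`.
#' @param means optional named per-variant imputation means.
#' @return named numeric vector of scores.
#' @export
prs_score <- function(genotypes, model, means = NULL) {
  if (length(model$ids) == 0) {
    sc <- setNames(numeric(nrow(genotypes$dosages)),
                   rownames(genotypes$dosages))
    return(structure(sc, n_absent = 0L))
  }
  j <- match(model$ids, genotypes$variant_info$id)
  present <- !is.na(j)
  d <- genotypes$dosages[, j[present], drop = FALSE]
  mns <- if (is.null(means)) NULL
         else if (!is.null(names(means)))
           unname(means[genotypes$variant_info$id[j[present]]])
         else means[j[present]]
  d <- impute_mean(d, means = mns)$imputed
  sc <- drop(d %*% model$weights[present])
  names(sc) <- rownames(genotypes$dosages)
  structure(sc, n_absent = sum(!present))
}

#' Build block LD matrices from reference genotypes
#'
#' Variants are chunked per chromosome into blocks of at most
#' `max_block_variants`; each block stores the Pearson correlation matrix of
#' mean-imputed dosages plus the dosage standard deviations used to map
#' standardized effects back to the dosage scale.
#'
#' @param genotypes reference [genotype_matrix()] (training fold).
#' @param max_block_variants maximum block size.
#' @return list of blocks: `ids`, `R`, `sd`.
#' @export
build_ld_blocks <- function(genotypes, max_block_variants = 100) {
  vi <- genotypes$variant_info
  out <- list()
  for (ch in unique(vi$chrom)) {
    idx <- which(vi$chrom == ch)
    starts <- seq(1, length(idx), by = max_block_variants)
    for (s in starts) {
      jj <- idx[s:min(s + max_block_variants - 1, length(idx))]
      d <- impute_mean(genotypes$dosages[, jj, drop = FALSE])$imputed
      R <- suppressWarnings(cor(d))
      R[!is.finite(R)] <- 0
      diag(R) <- 1
      out[[length(out) + 1]] <-
        list(ids = vi$id[jj], R = R, sd = apply(d, 2, sd))
    }
  }
  out
}

#' Marginal dosage-phenotype correlations
#'
#' @param genotypes training [genotype_matrix()].
#' @param status binary phenotype.
#' @return named vector of correlations (0 for monomorphic variants).
#' @export
marginal_correlations <- function(genotypes, status) {
  d <- impute_mean(genotypes$dosages)$imputed
  r <- suppressWarnings(cor(d, status))[, 1]
  r[!is.finite(r)] <- 0
  setNames(r, genotypes$variant_info$id)
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

lassosum_block <- function(R, r, lambda, s, max_sweeps = 10000,
                           tol = 1e-8) {
  out <- lassosum_cd_cpp(R, as.numeric(r), lambda, s, max_sweeps, tol)
  list(beta = drop(out$beta), objective = out$objective,
       converged = out$converged)
}

#' L1-penalized summary-statistic polygenic score
#'
#' Per block, minimizes
#' `(1-s) b'Rb + s b'b - 2 b'r + 2 lambda ||b||_1`
#' by cyclic coordinate descent (the unit diagonal makes each coordinate
#' update a single soft-threshold). When training genotypes and status are
#' supplied, `(lambda, s)` is chosen by AUC on a seeded inner 80/20 split;
#' otherwise the first grid point is used.
#'
#' @param r named marginal correlations (aligned to blocks).
#' @param blocks LD blocks from [build_ld_blocks()].
#' @param lambda_grid,s_grid hyperparameter grids (`s` in (0, 1]).
#' @param genotypes_train,status_train training fold for tuning (optional).
#' @param fold fold id.
#' @param seed inner-split seed.
#' @return a `prs_model` with weights on the dosage scale.
#' @export
lassosum_fit <- function(r, blocks,
                         lambda_grid = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1),
                         s_grid = c(0.2, 0.5, 0.9, 1),
                         genotypes_train = NULL, status_train = NULL,
                         fold = NA, seed = 1) {
  stopifnot(all(s_grid > 0), all(s_grid <= 1), all(abs(r) <= 1 + 1e-8))
  solve_all <- function(lambda, s) {
    betas <- conv <- NULL
    out <- lapply(blocks, function(b)
      lassosum_block(b$R, r[b$ids], lambda, s))
    list(ids = unlist(lapply(blocks, `[[`, "ids")),
         beta = unlist(lapply(out, `[[`, "beta")),
         sd = unlist(lapply(blocks, `[[`, "sd")),
         converged = all(vapply(out, `[[`, TRUE, "converged")))
  }
  tune <- !is.null(genotypes_train) && !is.null(status_train)
  grid <- expand.grid(lambda = lambda_grid, s = s_grid)
  if (!tune) grid <- grid[1, , drop = FALSE]
  inner <- if (tune) stratified_split(status_train, 0.8, seed) else NULL
  means <- if (tune)
    colMeans(genotypes_train$dosages[inner, , drop = FALSE], na.rm = TRUE)
  best <- NULL
  for (gi in seq_len(nrow(grid))) {
    sol <- solve_all(grid$lambda[gi], grid$s[gi])
    w <- ifelse(sol$sd > 0, sol$beta / sol$sd, 0)
    mod <- new_prs_model("lassosum", sol$ids, w,
                         list(lambda = grid$lambda[gi], s = grid$s[gi],
                              converged = sol$converged),
                         fold, NULL, scale = "standardized")
    a <- if (tune) {
      sc <- prs_score(gt_subset(genotypes_train, samples = which(!inner)),
                      mod, means = means)
      if (length(unique(status_train[!inner])) < 2) 0.5
      else auc(sc, status_train[!inner])
    } else 1
    if (is.null(best) || a > best$auc + 1e-12)
      best <- list(auc = a, mod = mod)
  }
  m <- best$mod
  m$hyper$inner_auc <- if (tune) best$auc else NA
  m$train_ids <- if (tune) rownames(genotypes_train$dosages) else NULL
  m
}

#' Infinitesimal-prior polygenic score
#'
#' Closed-form shrinkage of standardized marginal effects through
#' regularized block LD: per block, `b = (R + M/(N h2) I)^{-1} b_marginal`.
#' Deterministic stand-in for Gibbs-sampled infinitesimal models at desk
#' scale.
#'
#' @param beta_marginal named standardized marginal effects (correlations).
#' @param blocks LD blocks from [build_ld_blocks()].
#' @param h2 assumed SNP heritability in (0, 1].
#' @param M total variant count; defaults to `length(beta_marginal)`.
#' @param N training sample count.
#' @param fold fold id.
#' @param train_ids training sample ids for the leakage contract.
#' @return a `prs_model` with weights on the dosage scale.
#' @export
inf_fit <- function(beta_marginal, blocks, h2, M = length(beta_marginal), N,
                    fold = NA, train_ids = NULL) {
  stopifnot(h2 > 0, h2 <= 1, N >= 1)
  shrink <- M / (N * h2)
  ids <- unlist(lapply(blocks, `[[`, "ids"))
  beta <- unlist(lapply(blocks, function(b) {
    A <- b$R + diag(shrink, length(b$ids))
    out <- tryCatch(solve(A, beta_marginal[b$ids]),
                    error = function(e)
                      stop("singular regularized LD block"))
    out
  }))
  sds <- unlist(lapply(blocks, `[[`, "sd"))
  w <- ifelse(sds > 0, beta / sds, 0)
  new_prs_model("inf", ids, w, list(h2 = h2, M = M, N = N), fold,
                train_ids, scale = "standardized")
}
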