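#' Cross-validation pipeline configuration
#'
#' @param n_folds folds (default 10).
#' @param n_pcs principal components used as covariates.
#' @param seed master seed; per-fold and per-model streams are derived.
#' @param fs_methods feature-selection strategies to run.
#' @param k_grid panel sizes (ascending).
#' @param models classifier algorithms for genotype/risk-factor sets.
#' @param prs_methods polygenic-score constructions to run.
#' @param feature_sets explicit cell list; NULL builds the default layout
#'   (risk factors; all pruned SNPs; each PRS alone and with risk factors;
#'   each top-k panel with risk factors and PCs).
#' @param fs_stat association statistic ranking the `gwas` method
#'   (`fisher` allelic or `logistic` Wald p).
#' @param fs_conf an [fs_config()].
#' @param prs_h2 assumed heritability for the infinitesimal PRS.
#' @param pt_thresholds p-value grid for clumping+thresholding.
#' @param lassosum_lambda,lassosum_s lassosum hyperparameter grids.
#' @param ld_block_size variants per LD block for summary-statistic PRS.
#' @param stability_k panel size for the stability analysis.
#' @param stable_threshold minimum selection count for the stable set.
#' @param categorical_covariates covariate names treated as factors.
#' @param run_vif screen covariates by variance inflation before use.
#' @param vif_threshold VIF removal threshold.
#' @return `cv_config` list.
#' @export
cv_config <- function(n_folds = 10, n_pcs = 20, seed = 1,
                      fs_methods = c("gwas", "mrmr", "rf"),
                      k_grid = c(5, 10, 15, 20, 50),
                      models = c("logistic", "lasso_logistic", "svm_rbf",
                                 "random_forest"),
                      prs_methods = c("pt", "lassosum", "inf"),
                      feature_sets = NULL,
                      fs_stat = c("fisher", "logistic"),
                      fs_conf = fs_config(k_grid = k_grid),
                      prs_h2 = 0.5,
                      pt_thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                        0.1, 0.5, 1),
                      lassosum_lambda = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1),
                      lassosum_s = c(0.2, 0.5, 0.9, 1),
                      ld_block_size = 100,
                      stability_k = 50, stable_threshold = 5,
                      categorical_covariates = c("batch", "center"),
                      run_vif = TRUE, vif_threshold = 10) {
  fs_stat <- match.arg(fs_stat)
  stopifnot(!is.unsorted(k_grid), n_folds >= 2)
  structure(as.list(environment()), class = "cv_config")
}

default_feature_sets <- function(config) {
  fs_models <- intersect(c("lasso_logistic", "svm_rbf", "random_forest"),
                         config$models)
  if (!length(fs_models)) fs_models <- config$models
  sets <- list(
    list(name = "risk_factors", genotype = "none", riskfactors = TRUE,
         pcs = TRUE, prs = NA, models = config$models),
    list(name = "all_snps", genotype = "all", riskfactors = FALSE,
         pcs = FALSE, prs = NA, models = config$models)
  )
  for (pm in config$prs_methods) {
    sets[[length(sets) + 1]] <-
      list(name = paste0("prs_", pm), genotype = "none",
           riskfactors = FALSE, pcs = FALSE, prs = pm, models = "logistic")
    sets[[length(sets) + 1]] <-
      list(name = paste0("prs_", pm, "_rf"), genotype = "none",
           riskfactors = TRUE, pcs = TRUE, prs = pm, models = "logistic")
  }
  for (fm in config$fs_methods) for (k in config$k_grid) {
    sets[[length(sets) + 1]] <-
      list(name = sprintf("top%d_%s", k, fm), genotype = "topk",
           fs_method = fm, k = k, riskfactors = TRUE, pcs = TRUE,
           prs = NA, models = fs_models)
  }
  sets
}

#' Quality-control and prepare a cohort for cross-validation
#'
#' Applies, once and before any fold split: greedy relatedness removal,
#' sample missingness filtering, the variant filter chain, windowed LD
#' pruning, and optional control balancing.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype table (`sample_id`, `status`, covariates).
#' @param thresholds a [qc_thresholds()].
#' @param balance subsample controls to `target_ratio` per case.
#' @param target_ratio controls per case after balancing.
#' @param seed RNG seed for balancing.
#' @param kinship_markers kinship is estimated on an evenly thinned subset
#'   of at most this many markers, the usual practice for relatedness
#'   screens; the estimator's null spread scales as `1/sqrt(markers)`.
#' @return list with `genotypes`, `phenotypes` and `reports`.
#' @export
prepare_dataset <- function(genotypes, phenotypes,
                            thresholds = qc_thresholds(), balance = TRUE,
                            target_ratio = 1.0, seed = 1,
                            kinship_markers = 2000) {
  reports <- list()
  m_all <- ncol(genotypes$dosages)
  kin_idx <- unique(round(seq(1, m_all,
                              length.out = min(m_all, kinship_markers))))
  rel <- remove_related(gt_subset(genotypes, variants = kin_idx),
                        thresholds$kinship_max,
                        thresholds$kinship_min_overlap)
  reports$relatedness <- rel
  genotypes <- gt_subset(genotypes, samples = rel$retained)
  fs <- filter_samples(genotypes, thresholds)
  reports$samples <- fs$report
  genotypes <- fs$genotypes
  fv <- filter_variants(genotypes, thresholds)
  reports$variants <- fv$report
  genotypes <- fv$genotypes
  pruned <- ld_prune(genotypes, thresholds)
  reports$pruning <- list(n_before = ncol(genotypes$dosages),
                          n_after = length(pruned))
  genotypes <- gt_subset(genotypes, variants = pruned)
  phenotypes <- phenotypes[match(rownames(genotypes$dosages),
                                 phenotypes$sample_id), , drop = FALSE]
  if (balance) {
    keep <- balance_controls(phenotypes$status, phenotypes$sample_id,
                             target_ratio, child_seed(seed, 7))
    genotypes <- gt_subset(genotypes, samples = keep)
    phenotypes <- phenotypes[match(keep, phenotypes$sample_id), ,
                             drop = FALSE]
  }
  rownames(phenotypes) <- NULL
  list(genotypes = genotypes, phenotypes = phenotypes, reports = reports)
}

riskfactor_frame <- function(phenotypes, categorical) {
  cv <- phenotypes[, setdiff(names(phenotypes), c("sample_id", "status")),
                   drop = FALSE]
  for (nm in intersect(categorical, names(cv)))
    cv[[nm]] <- factor(cv[[nm]])
  cv
}

#' Run the full leakage-free cross-validation comparison
#'
#' For each fold: principal components, the covariate-adjusted association
#' scan, the three feature-selection rankings and the polygenic-score
#' models are recomputed on training samples only; every classifier is
#' fitted on training features (imputation statistics learned on the
#' training fold) and evaluated by AUC on the held-out fold. Scoring a
#' sample with a model whose training fold contained it is a hard error.
#'
#' @param genotypes QC'd, LD-pruned [genotype_matrix()]
#'   (see [prepare_dataset()]).
#' @param phenotypes aligned phenotype table.
#' @param config a [cv_config()].
#' @return `cv_report`: `cells` (fold x feature-set x model AUCs),
#'   `selections`, `stability`, `frequency`, `stable_sets`, `consensus`,
#'   `prs_hyper`, `fold_plan`, `vif`, `config`.
#' @export
run_cv_pipeline <- function(genotypes, phenotypes, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  phenotypes <- phenotypes[match(rownames(genotypes$dosages),
                                 phenotypes$sample_id), , drop = FALSE]
  if (anyNA(phenotypes$status)) stop("missing status")
  status <- phenotypes$status
  sex <- if ("sex" %in% names(phenotypes)) phenotypes$sex
         else rep(0L, length(status))
  plan <- make_folds(status, sex, config$n_folds, child_seed(config$seed, 11))
  cvfr <- riskfactor_frame(phenotypes, config$categorical_covariates)
  Xrf_all <- covariate_matrix(cvfr)
  vif <- NULL
  if (config$run_vif && ncol(Xrf_all) >= 2) {
    vif <- vif_screen(Xrf_all, config$vif_threshold)
    Xrf_all <- Xrf_all[, vif$retained, drop = FALSE]
  }
  feature_sets <- config$feature_sets
  if (is.null(feature_sets)) feature_sets <- default_feature_sets(config)
  k_for_method <- max(config$k_grid)
  sel <- list()
  for (fm in config$fs_methods) sel[[fm]] <-
    lapply(config$k_grid, function(k) vector("list", config$n_folds))
  rows <- list()
  prs_hyper <- list()
  ids_all <- rownames(genotypes$dosages)

  need_logistic <- length(config$prs_methods) > 0 ||
    ("gwas" %in% config$fs_methods && config$fs_stat == "logistic")
  need_pca <- config$n_pcs > 0 &&
    (need_logistic ||
       any(vapply(feature_sets, function(s) isTRUE(s$pcs), TRUE)))

  for (f in seq_len(config$n_folds)) {
    tr <- plan$fold != f
    te <- !tr
    gt_tr <- gt_subset(genotypes, samples = which(tr))
    gt_te <- gt_subset(genotypes, samples = which(te))
    y_tr <- status[tr]; y_te <- status[te]
    if (length(unique(y_te)) < 2) stop("test fold lacks both classes")
    g_means <- colMeans(gt_tr$dosages, na.rm = TRUE)
    pcs_tr <- pcs_te <- NULL
    if (need_pca) {
      pca <- genotype_pca(gt_tr, config$n_pcs,
                          seed = child_seed(config$seed, 100 + f))
      pcs_tr <- pca$scores
      pcs_te <- pc_project(pca, gt_te)
    }
    covars_tr <- cvfr[tr, , drop = FALSE]
    stats_log <- if (need_logistic)
      logistic_gwas(gt_tr, y_tr, covariates = covars_tr, pcs = pcs_tr)
    rankings <- list()
    if ("gwas" %in% config$fs_methods) {
      st <- if (config$fs_stat == "fisher") fisher_scan(gt_tr, y_tr)
            else stats_log
      rankings$gwas <- rank_by_gwas(st, fold = f)
    }
    if ("mrmr" %in% config$fs_methods) {
      ncand <- min(config$fs_conf$mrmr_prescreen, ncol(gt_tr$dosages))
      rel <- mi_columns(mrmr_code(gt_tr$dosages), y_tr)
      pool <- gt_tr$variant_info$id[order(-rel, gt_tr$variant_info$id)]
      pool <- sort(head(pool, ncand))
      rankings$mrmr <- mrmr_select(gt_tr, y_tr,
                                   k = min(k_for_method, ncand),
                                   candidates = pool, fold = f)
    }
    if ("rf" %in% config$fs_methods) {
      fsc <- config$fs_conf
      fsc$seed <- child_seed(config$seed, 200 + f)
      rankings$rf <- rf_importance_rank(gt_tr, y_tr, fsc, fold = f)
    }
    for (fm in names(rankings)) for (ki in seq_along(config$k_grid)) {
      k <- config$k_grid[ki]
      if (k <= nrow(rankings[[fm]]))
        sel[[fm]][[ki]][[f]] <- select_top_k(rankings[[fm]], k)
    }
    prs_models <- list()
    if (length(config$prs_methods)) {
      if ("pt" %in% config$prs_methods)
        prs_models$pt <- pt_fit(stats_log, gt_tr, y_tr,
                                thresholds = config$pt_thresholds,
                                fold = f, seed = child_seed(config$seed, 300 + f))
      if (any(c("lassosum", "inf") %in% config$prs_methods)) {
        blocks <- build_ld_blocks(gt_tr, config$ld_block_size)
        rmarg <- marginal_correlations(gt_tr, y_tr)
        if ("lassosum" %in% config$prs_methods)
          prs_models$lassosum <- lassosum_fit(
            rmarg, blocks, config$lassosum_lambda, config$lassosum_s,
            genotypes_train = gt_tr, status_train = y_tr, fold = f,
            seed = child_seed(config$seed, 400 + f))
        if ("inf" %in% config$prs_methods)
          prs_models$inf <- inf_fit(rmarg, blocks, h2 = config$prs_h2,
                                    N = sum(tr), fold = f,
                                    train_ids = rownames(gt_tr$dosages))
      }
      prs_hyper[[f]] <- lapply(prs_models, `[[`, "hyper")
      te_ids <- rownames(gt_te$dosages)
      for (pm in names(prs_models)) {
        mt <- prs_models[[pm]]$train_ids
        if (!is.null(mt) && any(te_ids %in% mt))
          stop("leakage: test sample present in PRS training fold")
      }
    }
    prs_scores_tr <- lapply(prs_models, function(mo)
      prs_score(gt_tr, mo, means = g_means))
    prs_scores_te <- lapply(prs_models, function(mo)
      prs_score(gt_te, mo, means = g_means))

    assemble <- function(fset, which_rows) {
      is_tr <- identical(which_rows, "train")
      parts <- list()
      if (fset$genotype == "all") {
        d <- if (is_tr) gt_tr$dosages else gt_te$dosages
        parts$g <- impute_mean(d, means = g_means)$imputed
      } else if (fset$genotype == "topk") {
        rk <- rankings[[fset$fs_method]]
        if (is.null(rk) || fset$k > nrow(rk)) return(NULL)
        ids <- select_top_k(rk, fset$k)
        j <- match(ids, genotypes$variant_info$id)
        d <- if (is_tr) gt_tr$dosages[, j, drop = FALSE]
             else gt_te$dosages[, j, drop = FALSE]
        parts$g <- impute_mean(d, means = g_means[j])$imputed
      }
      if (!is.na(fset$prs)) {
        s <- if (is_tr) prs_scores_tr[[fset$prs]] else prs_scores_te[[fset$prs]]
        if (is.null(s)) return(NULL)
        parts$prs <- matrix(s, ncol = 1, dimnames = list(NULL, "PRS"))
      }
      if (isTRUE(fset$riskfactors))
        parts$rf <- if (is_tr) Xrf_all[tr, , drop = FALSE]
                    else Xrf_all[te, , drop = FALSE]
      if (isTRUE(fset$pcs) && !is.null(pcs_tr))
        parts$pcs <- if (is_tr) pcs_tr else pcs_te
      if (!length(parts)) return(NULL)
      do.call(cbind, parts)
    }

    mi_seed <- 0L
    for (fset in feature_sets) {
      Ftr <- assemble(fset, "train")
      Fte <- assemble(fset, "test")
      for (mdl in fset$models) {
        mi_seed <- mi_seed + 1L
        if (is.null(Ftr) || is.null(Fte)) {
          rows[[length(rows) + 1]] <-
            data.frame(fold = f, feature_set = fset$name, model = mdl,
                       k = if (!is.null(fset$k)) fset$k else NA_integer_,
                       auc = NA_real_, flag = "unavailable")
          next
        }
        spec <- classifier_spec(mdl,
                                seed = child_seed(config$seed,
                                                  1000L + f * 50L + mi_seed))
        clf <- train_classifier(Ftr, y_tr, spec)
        sc <- predict_scores(clf, Fte)
        rows[[length(rows) + 1]] <-
          data.frame(fold = f, feature_set = fset$name, model = mdl,
                     k = if (!is.null(fset$k)) fset$k else NA_integer_,
                     auc = auc(sc, y_te), flag = clf$flag)
      }
    }
  }

  cells <- if (length(rows)) do.call(rbind, rows)
           else data.frame(fold = integer(0), feature_set = character(0),
                           model = character(0), k = integer(0),
                           auc = numeric(0), flag = character(0))
  rownames(cells) <- NULL
  stability <- do.call(rbind, lapply(names(sel), function(fm) {
    do.call(rbind, lapply(seq_along(config$k_grid), function(ki) {
      sets <- Filter(Negate(is.null), sel[[fm]][[ki]])
      if (length(sets) < 2) return(NULL)
      data.frame(method = fm, k = config$k_grid[ki],
                 overlap_pct = overlap_percentage(sets, config$k_grid[ki]))
    }))
  }))
  ki_stab <- match(config$stability_k, config$k_grid)
  freq <- list(); stable_sets <- list()
  if (!is.na(ki_stab)) {
    for (fm in names(sel)) {
      sets <- Filter(Negate(is.null), sel[[fm]][[ki_stab]])
      fr <- selection_frequency(sets, config$stable_threshold)
      freq[[fm]] <- fr$counts
      stable_sets[[fm]] <- fr$stable
    }
  }
  consensus <- if (length(stable_sets)) consensus_variants(stable_sets)
               else character(0)
  structure(list(cells = cells, selections = sel, stability = stability,
                 frequency = freq, stable_sets = stable_sets,
                 consensus = consensus, prs_hyper = prs_hyper,
                 fold_plan = plan, vif = vif, config = config),
            class = "cv_report")
}

mrmr_code <- function(d) {
  if (anyNA(d)) {
    mm <- round(colMeans(d, na.rm = TRUE))
    idx <- which(is.na(d))
    d[idx] <- mm[((idx - 1L) %/% nrow(d)) + 1L]
  }
  storage.mode(d) <- "integer"
  d
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d folds, %d cells\n",
              x$fold_plan$n_folds, nrow(x$cells)))
  if (nrow(x$cells)) {
    agg <- stats::aggregate(auc ~ feature_set + model, data = x$cells, mean)
    print(agg, row.names = FALSE)
  }
  if (length(x$consensus))
    cat("consensus variants:", paste(x$consensus, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy per-cell AUC table
#'
#' @param report a `cv_report`.
#' @return data.frame (FOLD, MODEL, FEATURESET, K, AUC, FLAG).
#' @export
cv_cells <- function(report) {
  data.frame(FOLD = report$cells$fold, MODEL = report$cells$model,
             FEATURESET = report$cells$feature_set, K = report$cells$k,
             AUC = report$cells$auc, FLAG = report$cells$flag)
}
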