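#' Subsample controls to a target case:control ratio
#'
#' All cases are kept; controls are drawn uniformly without replacement.
#'
#' @param status binary vector (case = 1).
#' @param sample_ids ids aligned to `status`.
#' @param target_ratio controls retained per case.
#' @param seed RNG seed.
#' @return retained sample ids (original order).
#' @export
balance_controls <- function(status, sample_ids, target_ratio = 1.0,
                             seed = 1) {
  stopifnot(length(status) == length(sample_ids))
  cases <- which(status == 1)
  ctrls <- which(status == 0)
  n_keep <- round(length(cases) * target_ratio)
  if (length(ctrls) < n_keep) stop("insufficient controls for target ratio")
  keep_ctrl <- with_seed(seed, sample(ctrls, n_keep))
  sample_ids[sort(c(cases, keep_ctrl))]
}

#' Stratified cross-validation fold plan
#'
#' Within each (status, sex) stratum: seeded shuffle, then round-robin
#' assignment, so per-stratum fold counts differ by at most one.
#'
#' @param status binary phenotype.
#' @param sex binary covariate (second stratification key).
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return `fold_plan` list: `fold` (per-sample id in 1..n_folds),
#'   `n_folds`, `seed`, `flagged` (TRUE when a stratum was smaller than
#'   `n_folds`).
#' @export
make_folds <- function(status, sex, n_folds = 10, seed = 1) {
  stopifnot(length(status) == length(sex))
  strata <- interaction(status, sex, drop = TRUE)
  fold <- integer(length(status))
  flagged <- FALSE
  with_seed(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      if (length(idx) < n_folds) {
        warning("stratum ", s, " smaller than n_folds; best-effort assignment")
        flagged <- TRUE
      }
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                    length(idx))
    }
  })
  structure(list(fold = fold, n_folds = n_folds, seed = seed,
                 flagged = flagged), class = "fold_plan")
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `(concordant pairs + 0.5 tied pairs) / (n1 * n0)`, computed via midranks.
#'
#' @param scores continuous scores.
#' @param labels binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classifier specification
#'
#' @param algorithm one of `logistic`, `lasso_logistic`, `svm_rbf`,
#'   `random_forest`.
#' @param seed RNG seed (forest, inner splits).
#' @param rf_trees,rf_mtry forest size and per-split feature cap.
#' @param svm_cost,svm_gamma RBF-SVM cost and kernel width (`NULL` gives
#'   `1/ncol`).
#' @param ridge_lambda penalty for the logistic model when fitted as
#'   L2-regularized (`NULL` gives `1/n`, the liblinear-default equivalent).
#' @return `classifier_spec` list.
#' @export
classifier_spec <- function(algorithm = c("logistic", "lasso_logistic",
                                          "svm_rbf", "random_forest"),
                            seed = 1, rf_trees = 500, rf_mtry = 35,
                            svm_cost = 1, svm_gamma = NULL,
                            ridge_lambda = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(rf_trees > 0, rf_mtry > 0, svm_cost > 0)
  structure(as.list(environment()), class = "classifier_spec")
}

#' Train a binary classifier exposing a continuous score
#'
#' Logistic regression is fitted as L2-regularized maximum likelihood
#' (penalty `1/n`, matching common solver defaults); the lasso penalty is
#' chosen on a seeded inner 80/20 split over the regularization path; the
#' RBF-SVM uses fixed cost and kernel width; the forest is a probability
#' forest. All-constant feature blocks trigger a flagged majority-score
#' fallback.
#'
#' @param features numeric matrix (training fold, complete).
#' @param labels binary labels.
#' @param spec a [classifier_spec()].
#' @return `fitted_classifier` with a `flag` field; score held-out data with
#'   [predict_scores()].
#' @export
train_classifier <- function(features, labels, spec) {
  stopifnot(nrow(features) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("single-class labels")
  keep <- apply(features, 2, function(x) var(x) > 0)
  if (!any(keep)) {
    return(structure(list(algorithm = spec$algorithm, fit = NULL,
                          flag = "degenerate_features",
                          fallback = mean(labels), keep = keep),
                     class = "fitted_classifier"))
  }
  X <- features[, keep, drop = FALSE]
  if (spec$algorithm %in% c("logistic", "lasso_logistic") && ncol(X) == 1) {
    # single predictor: penalization is moot, fit plain maximum likelihood
    fit <- glm.fit(cbind(1, X), labels, family = binomial())
    return(structure(list(algorithm = "glm1", fit = coef(fit), flag = "ok",
                          keep = keep),
                     class = "fitted_classifier"))
  }
  fit <- switch(spec$algorithm,
    logistic = {
      lam <- if (is.null(spec$ridge_lambda)) 1 / nrow(X) else spec$ridge_lambda
      glmnet::glmnet(X, labels, family = "binomial", alpha = 0,
                     lambda = lam, standardize = TRUE)
    },
    lasso_logistic = {
      inner <- stratified_split(labels, 0.8, spec$seed)
      path <- suppressWarnings(
        glmnet::glmnet(X[inner, , drop = FALSE], labels[inner],
                       family = "binomial", alpha = 1, nlambda = 30))
      pv <- suppressWarnings(predict(path, X[!inner, , drop = FALSE]))
      aucs <- apply(pv, 2, function(s)
        if (length(unique(labels[!inner])) < 2) 0.5
        else auc(s, labels[!inner]))
      lam <- path$lambda[which.max(aucs)]
      glmnet::glmnet(X, labels, family = "binomial", alpha = 1, lambda = lam)
    },
    svm_rbf = {
      gam <- if (is.null(spec$svm_gamma)) 1 / ncol(X) else spec$svm_gamma
      e1071::svm(x = X, y = factor(labels), kernel = "radial",
                 cost = spec$svm_cost, gamma = gam, scale = TRUE)
    },
    random_forest = {
      ranger::ranger(x = X, y = factor(labels),
                     num.trees = spec$rf_trees,
                     mtry = min(spec$rf_mtry, ncol(X)),
                     probability = TRUE, seed = spec$seed,
                     num.threads = 1, verbose = FALSE)
    })
  structure(list(algorithm = spec$algorithm, fit = fit, flag = "ok",
                 keep = keep),
            class = "fitted_classifier")
}

#' Score held-out samples with a fitted classifier
#'
#' @param clf a `fitted_classifier`.
#' @param features numeric matrix with the training columns.
#' @return numeric score vector (probability or margin).
#' @export
predict_scores <- function(clf, features) {
  if (clf$flag == "degenerate_features")
    return(rep(clf$fallback, nrow(features)))
  X <- features[, clf$keep, drop = FALSE]
  switch(clf$algorithm,
    glm1 = drop(stats::plogis(cbind(1, X) %*% clf$fit)),
    logistic = ,
    lasso_logistic = drop(predict(clf$fit, X, type = "response")),
    svm_rbf = {
      pv <- predict(clf$fit, X, decision.values = TRUE)
      dv <- drop(attr(pv, "decision.values"))
      # orient the margin toward class "1"
      if (grepl("^0", colnames(attr(pv, "decision.values"))[1])) -dv else dv
    },
    random_forest = predict(clf$fit, X, num.threads = 1,
                            verbose = FALSE)$predictions[, "1"])
}

#' Mean pairwise top-k overlap percentage
#'
#' Mean over unordered fold pairs of `|S_i intersect S_j| / k * 100`. With
#' `common_fraction = TRUE`, instead returns the percentage of variants
#' common to all sets relative to `k`.
#'
#' @param sets list of top-k id vectors (one per fold).
#' @param k panel size.
#' @param common_fraction alternative all-folds-common metric.
#' @return percentage in `[0, 100]`.
#' @export
overlap_percentage <- function(sets, k, common_fraction = FALSE) {
  stopifnot(length(sets) >= 2, all(vapply(sets, length, 0L) <= k))
  if (common_fraction)
    return(100 * length(Reduce(intersect, sets)) / k)
  n <- length(sets)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + length(intersect(sets[[i]], sets[[j]])) / k
    np <- np + 1
  }
  100 * tot / np
}

#' Per-variant selection frequency across folds
#'
#' @param sets list of per-fold selected id vectors.
#' @param threshold minimum count for the stable set (default 5 of 10).
#' @return list with `counts` (named, decreasing) and `stable` ids.
#' @export
selection_frequency <- function(sets, threshold = 5) {
  all_ids <- unlist(sets)
  counts <- sort(table(all_ids), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts, stable = names(counts)[counts >= threshold])
}

#' Cross-method consensus variants
#'
#' Intersection of the per-method stable sets.
#'
#' @param stable_sets list of id vectors, one per feature-selection method.
#' @return character vector of consensus variant ids.
#' @export
consensus_variants <- function(stable_sets) {
  stopifnot(length(stable_sets) >= 1)
  sort(Reduce(intersect, stable_sets))
}
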