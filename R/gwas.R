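#' One-hot encode a covariate table
#'
#' Characters and factors expand to treatment-coded dummies; numeric columns
#' pass through. No intercept column.
#'
#' @param covariates data.frame.
#' @return numeric matrix.
#' @export
covariate_matrix <- function(covariates) {
  df <- as.data.frame(covariates)
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  mm <- model.matrix(~ . , data = df)
  mm[, -1, drop = FALSE]
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per variant; dosages are standardized as
#' `(g - 2p) / sqrt(2p(1-p))` with `p` the sample alt-allele frequency;
#' scores come from a truncated SVD (exact for small matrices, randomized
#' subspace iteration otherwise, deterministic under `seed`). Sign
#' convention: each component's largest-magnitude loading is positive.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n_pcs number of components (default 20).
#' @param seed seed for the randomized projection.
#' @return `pc_result` list: `scores` (n x k), `loadings` (m x k),
#'   `explained` variance fractions (nonincreasing), `freqs` used for
#'   standardization.
#' @export
genotype_pca <- function(genotypes, n_pcs = 20, seed = 1) {
  d <- genotypes$dosages
  n_pcs <- min(n_pcs, nrow(d), ncol(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  A <- standardize_dosages(d, p)
  if (all(A == 0)) stop("degenerate matrix: zero variance everywhere")
  total <- sum(A^2)
  k <- n_pcs
  if (min(dim(A)) <= 600) {
    sv <- svd(A, nu = k, nv = k)
    dvals <- sv$d[seq_len(k)]
    U <- sv$u; V <- sv$v
  } else {
    L <- min(k + 10, min(dim(A)))
    with_seed(seed, {
      Om <- matrix(rnorm(ncol(A) * L), ncol(A), L)
    })
    Y <- A %*% Om
    for (q in 1:2) {
      Y <- qr.Q(qr(Y))
      Y <- A %*% crossprod(A, Y)
    }
    Q <- qr.Q(qr(Y))
    B <- crossprod(Q, A)
    sb <- svd(B)
    dvals <- sb$d[seq_len(k)]
    U <- Q %*% sb$u[, seq_len(k), drop = FALSE]
    V <- sb$v[, seq_len(k), drop = FALSE]
  }
  for (i in seq_len(k)) {
    top <- which.max(abs(V[, i]))
    if (V[top, i] < 0) { V[, i] <- -V[, i]; U[, i] <- -U[, i] }
  }
  scores <- U %*% diag(dvals, k, k)
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(V) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = V,
                 explained = dvals^2 / total, freqs = p),
            class = "pc_result")
}

standardize_dosages <- function(d, p) {
  im <- impute_mean(d, means = 2 * p)
  A <- im$imputed
  sdv <- sqrt(2 * p * (1 - p))
  ok <- sdv > 0
  A <- sweep(A, 2, 2 * p)
  A[, ok] <- sweep(A[, ok, drop = FALSE], 2, sdv[ok], "/")
  A[, !ok] <- 0
  A
}

#' Project samples onto fitted principal components
#'
#' Uses the training-fold allele frequencies for standardization, so
#' held-out samples never inform the rotation.
#'
#' @param pc a `pc_result` from [genotype_pca()].
#' @param genotypes a [genotype_matrix()] over the same variants.
#' @return score matrix.
#' @export
pc_project <- function(pc, genotypes) {
  A <- standardize_dosages(genotypes$dosages, pc$freqs)
  s <- A %*% pc$loadings
  rownames(s) <- rownames(genotypes$dosages)
  s
}

#' Fisher's exact allelic association test
#'
#' Two-sided exact p for the allelic 2x2 table (two alleles per sample);
#' the odds ratio is the sample cross-product ratio, with a 0.5 Haldane
#' correction when any cell is zero (flagged).
#'
#' @param case_alt,case_ref alt/ref allele counts in cases.
#' @param ctrl_alt,ctrl_ref alt/ref allele counts in controls.
#' @return list with `or`, `p`, and `haldane` flag.
#' @export
fisher_allelic_test <- function(case_alt, case_ref, ctrl_alt, ctrl_ref) {
  stopifnot(case_alt >= 0, case_ref >= 0, ctrl_alt >= 0, ctrl_ref >= 0,
            case_alt + case_ref + ctrl_alt + ctrl_ref >= 1)
  tab <- matrix(c(case_alt, ctrl_alt, case_ref, ctrl_ref), 2)
  p <- fisher.test(tab)$p.value
  haldane <- any(tab == 0)
  h <- if (haldane) 0.5 else 0
  or <- ((case_alt + h) * (ctrl_ref + h)) / ((case_ref + h) * (ctrl_alt + h))
  list(or = or, p = p, haldane = haldane)
}

#' Per-variant Fisher allelic scan
#'
#' @param genotypes a [genotype_matrix()].
#' @param status binary vector aligned to samples.
#' @return `summary_stats` data.frame with `beta = log(OR)`.
#' @export
fisher_scan <- function(genotypes, status) {
  d <- genotypes$dosages
  vi <- genotypes$variant_info
  stopifnot(length(status) == nrow(d), length(unique(status)) == 2)
  case <- status == 1
  res <- lapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    ca <- sum(x[case], na.rm = TRUE)
    cr <- 2 * sum(!is.na(x[case])) - ca
    ta <- sum(x[!case], na.rm = TRUE)
    tr <- 2 * sum(!is.na(x[!case])) - ta
    ft <- fisher_allelic_test(ca, cr, ta, tr)
    c(log(ft$or), ft$p,
      ca / max(ca + cr, 1), ta / max(ta + tr, 1))
  })
  res <- do.call(rbind, res)
  structure(data.frame(id = vi$id, chrom = vi$chrom, pos = vi$pos,
                       beta = res[, 1], se = NA_real_, p = res[, 2],
                       af_case = res[, 3], af_ctrl = res[, 4],
                       converged = TRUE, stringsAsFactors = FALSE),
            class = c("summary_stats", "data.frame"))
}

#' Covariate-adjusted logistic association scan
#'
#' Per SNP, additive-dosage logistic regression with the shared covariate
#' block (plus optional principal components), fitted by Newton iteration to
#' gradient tolerance `tol` with an iteration cap; Wald p-values from
#' `z = beta / SE`. Missing dosages are mean-imputed per variant from these
#' samples. SNPs that fail to converge (including separated ones) carry the
#' sentinel `p = 1` and `converged = FALSE`.
#'
#' @param genotypes a [genotype_matrix()] (training-fold samples only).
#' @param status binary phenotype vector.
#' @param covariates optional data.frame (factors one-hot encoded).
#' @param pcs optional numeric matrix of principal-component scores.
#' @param tol Newton gradient tolerance.
#' @param maxit Newton iteration cap.
#' @return `summary_stats` data.frame: id, chrom, pos, beta, se, p,
#'   af_case, af_ctrl, converged.
#' @export
logistic_gwas <- function(genotypes, status, covariates = NULL, pcs = NULL,
                          tol = 1e-8, maxit = 25) {
  d <- genotypes$dosages
  vi <- genotypes$variant_info
  stopifnot(length(status) == nrow(d))
  if (length(unique(status)) < 2) stop("constant-status fold")
  X <- matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) X <- cbind(X, covariate_matrix(covariates))
  if (!is.null(pcs)) X <- cbind(X, as.matrix(pcs))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    drop <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("rank-deficient covariate block: ", paste(drop, collapse = ", "))
  }
  null_fit <- glm.fit(X, status, family = binomial())
  G <- impute_mean(d)$imputed
  sc <- logit_scan_cpp(X, as.numeric(status), G,
                       as.numeric(coef(null_fit)), tol, maxit)
  conv <- sc$converged == 1
  z <- ifelse(conv, sc$beta / sc$se, 0)
  p <- ifelse(conv, 2 * pnorm(-abs(z)), 1)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  case <- status == 1
  nc_case <- colSums(!is.na(d[case, , drop = FALSE]))
  nc_ctrl <- colSums(!is.na(d[!case, , drop = FALSE]))
  af_case <- colSums(d[case, , drop = FALSE], na.rm = TRUE) /
    pmax(2 * nc_case, 1)
  af_ctrl <- colSums(d[!case, , drop = FALSE], na.rm = TRUE) /
    pmax(2 * nc_ctrl, 1)
  structure(data.frame(id = vi$id, chrom = vi$chrom, pos = vi$pos,
                       beta = ifelse(conv, sc$beta, NA_real_),
                       se = ifelse(conv, sc$se, NA_real_),
                       p = p, af_case = af_case, af_ctrl = af_ctrl,
                       converged = conv, stringsAsFactors = FALSE),
            class = c("summary_stats", "data.frame"))
}

#' Variance-inflation-factor screening
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate `j` on the others;
#' covariates exceeding the threshold are removed iteratively, highest
#' first, until all pass. Perfect collinearity yields an infinite VIF and is
#' handled as a removal candidate.
#'
#' @param covariates numeric-encoded data.frame or matrix (>= 2 columns).
#' @param threshold VIF removal threshold (default 10).
#' @return list: `vif` (initial), `vif_final` (retained set), `correlation`
#'   (Pearson matrix), `retained`, `removed`.
#' @export
vif_screen <- function(covariates, threshold = 10) {
  X <- as.matrix(covariates)
  stopifnot(ncol(X) >= 2, is.numeric(X))
  vif_of <- function(X) {
    vapply(seq_len(ncol(X)), function(j) {
      fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      ssr <- sum(fit$residuals^2)
      sst <- sum((X[, j] - mean(X[, j]))^2)
      if (sst == 0) return(Inf)
      r2 <- 1 - ssr / sst
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  vif0 <- setNames(vif_of(X), colnames(X))
  keep <- colnames(X)
  removed <- character(0)
  repeat {
    if (length(keep) < 2) break
    v <- setNames(vif_of(X[, keep, drop = FALSE]), keep)
    if (max(v) <= threshold) break
    worst <- names(which.max(v))
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  vfin <- if (length(keep) >= 2)
    setNames(vif_of(X[, keep, drop = FALSE]), keep)
  else setNames(rep(1, length(keep)), keep)
  list(vif = vif0, vif_final = vfin,
       correlation = suppressWarnings(cor(X)),
       retained = keep, removed = removed)
}
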