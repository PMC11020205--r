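# Independent brute-force oracles used across the suite. Each recomputes the
# quantity from first principles by a different route than the package code.

make_gt <- function(d, pos = NULL, chrom = "1") {
  d <- as.matrix(d)
  storage.mode(d) <- "integer"
  m <- ncol(d)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  vi <- data.frame(id = sprintf("v%03d", seq_len(m)), chrom = chrom,
                   pos = as.integer(pos), ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  genotype_matrix(d, vi)
}

# exact conditional HWE p by explicit enumeration with summed-log factorials
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  lf <- function(n) if (n == 0) 0 else sum(log(seq_len(n)))
  N <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * N - nA
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  lp <- vapply(hs, function(h) {
    aa <- (nA - h) / 2; bb <- (na - h) / 2
    lf(N) - lf(aa) - lf(h) - lf(bb) + h * log(2) + lf(nA) + lf(na) -
      lf(2 * N)
  }, 0)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hs == n_Aa] * (1 + 1e-10)])
}

# two-sided Fisher exact p by direct hypergeometric enumeration
fisher_p_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  pr <- dhyper(xs, m1, m2, k)
  sum(pr[pr <= dhyper(a, m1, m2, k) * (1 + 1e-7)])
}

# AUC by explicit enumeration of all case-control pairs
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Hudson FST estimator (ratio of averages) over variants
hudson_fst <- function(dosages, labels) {
  stopifnot(length(unique(labels)) == 2)
  g1 <- dosages[labels == unique(labels)[1], , drop = FALSE]
  g2 <- dosages[labels == unique(labels)[2], , drop = FALSE]
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- is.finite(num) & is.finite(den) & den > 0
  sum(num[ok]) / sum(den[ok])
}

# plug-in mutual information recomputed with nested loops over a table
mi_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  out <- 0
  for (ux in unique(x)) for (uy in unique(y)) {
    pxy <- sum(x == ux & y == uy) / n
    if (pxy > 0)
      out <- out + pxy * log(pxy / (sum(x == ux) / n * sum(y == uy) / n))
  }
  out
}

# hand-simulated greedy clumping pass
clump_oracle <- function(stats, gt, r2_max, window_bp) {
  o <- order(stats$p, stats$id)
  state <- rep("pending", nrow(stats))
  for (i in o) {
    if (state[i] != "pending") next
    state[i] <- "index"
    for (j in seq_len(nrow(stats))) {
      if (state[j] != "pending") next
      if (stats$chrom[j] == stats$chrom[i] &&
          abs(stats$pos[j] - stats$pos[i]) <= window_bp) {
        r2 <- ld_r2(gt$dosages[, match(stats$id[i], gt$variant_info$id)],
                    gt$dosages[, match(stats$id[j], gt$variant_info$id)])
        if (!is.na(r2) && r2 > r2_max) state[j] <- "removed"
      }
    }
  }
  stats$id[state == "index"][order(stats$p[state == "index"],
                                   stats$id[state == "index"])]
}

# lassosum objective value
lassosum_objective <- function(beta, R, r, lambda, s) {
  (1 - s) * drop(t(beta) %*% R %*% beta) + s * sum(beta^2) -
    2 * sum(beta * r) + 2 * lambda * sum(abs(beta))
}

# convex oracle for the lassosum block problem via glmnet on a synthetic
# design whose Gram matrix equals (1-s) R + s I
lassosum_glmnet_oracle <- function(R, r, lambda, s) {
  A <- (1 - s) * R + diag(s, nrow(R))
  m <- nrow(R)
  X <- sqrt(m) * chol(A)
  y <- drop(X %*% solve(A, r))
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lambda,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
  drop(as.matrix(coef(fit)))[-1]
}

# causal-or-proxy credit: a selected id counts if it is causal or shares an
# LD block with a causal variant
proxy_set <- function(truth, variant_info_all) {
  causal_blocks <- truth$block_ids[match(truth$causal_ids,
                                         variant_info_all$id)]
  variant_info_all$id[truth$block_ids %in% causal_blocks]
}
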