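#' Quality-control thresholds
#'
#' Defaults follow common biobank-scale practice: MAF >= 1%, per-marker and
#' per-sample missingness <= 20%, minor allele count >= 100, Hardy-Weinberg
#' exact p >= 1e-25, LD pruning in 500 kb windows advanced by 25 variants at
#' r^2 <= 0.1, and kinship cut at 0.0442 (third-degree relatives).
#'
#' @param maf_min minimum minor allele frequency.
#' @param variant_missing_max maximum per-variant missing fraction.
#' @param sample_missing_max maximum per-sample missing fraction.
#' @param mac_min minimum minor allele count.
#' @param hwe_p_min minimum Hardy-Weinberg exact p-value.
#' @param ld_window_bp LD-pruning window in base pairs.
#' @param ld_step_variants window advance in variants.
#' @param ld_r2_max maximum retained squared dosage correlation.
#' @param kinship_max maximum KING-robust kinship.
#' @param kinship_min_overlap minimum shared non-missing variants per pair.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, variant_missing_max = 0.2,
                          sample_missing_max = 0.2, mac_min = 100,
                          hwe_p_min = 1e-25, ld_window_bp = 500000,
                          ld_step_variants = 25, ld_r2_max = 0.1,
                          kinship_max = 0.0442, kinship_min_overlap = 50) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            variant_missing_max >= 0, variant_missing_max < 1,
            sample_missing_max >= 0, sample_missing_max < 1,
            mac_min >= 0, hwe_p_min >= 0, hwe_p_min <= 1,
            ld_window_bp > 0, ld_step_variants >= 1,
            ld_r2_max >= 0, ld_r2_max <= 1, kinship_max > 0)
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Minor allele frequency of a dosage column
#'
#' Alt-allele frequency over non-missing calls, folded to `<= 0.5`.
#'
#' @param dosages vector of 0/1/2/NA calls.
#' @return minor allele frequency.
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all calls missing: MAF undefined")
  p <- sum(dosages[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, enumerates every
#' attainable heterozygote count, and sums the probabilities of all genotype
#' configurations no more probable than the observed one (two-sided exact,
#' not mid-p).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  N <- n_AA + n_Aa + n_aa
  stopifnot(N >= 1)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hmax <- min(nA, na)
  h <- seq(hmax %% 2, hmax, by = 2)  # parity fixed by allele counts
  # P(h) = N! 2^h nA! na! / ( ((nA-h)/2)! h! ((na-h)/2)! (2N)! )
  logp <- lgamma(N + 1) + h * log(2) + lgamma(nA + 1) + lgamma(na + 1) -
    lgamma((nA - h) / 2 + 1) - lgamma(h + 1) - lgamma((na - h) / 2 + 1) -
    lgamma(2 * N + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

hwe_p_column <- function(dosages) {
  ok <- !is.na(dosages)
  hwe_exact_test(sum(dosages[ok] == 0), sum(dosages[ok] == 1),
                 sum(dosages[ok] == 2))
}

#' Variant-level filtering
#'
#' Applies, in order: missingness, MAF, MAC, Hardy-Weinberg exact test.
#' Counts are per filter stage, so they depend on the (recorded) order.
#'
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (filtered) and `report`.
#' @export
filter_variants <- function(genotypes, thresholds = qc_thresholds()) {
  d <- genotypes$dosages
  stopifnot(ncol(d) >= 1)
  ids <- genotypes$variant_info$id
  keep <- rep(TRUE, ncol(d))
  removed <- list()

  miss <- colMeans(is.na(d))
  bad <- keep & miss > thresholds$variant_missing_max
  removed$missingness <- ids[bad]; keep <- keep & !bad

  ncall <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  p <- ifelse(ncall > 0, alt / (2 * ncall), NA)
  maf <- pmin(p, 1 - p)
  bad <- keep & (is.na(maf) | maf < thresholds$maf_min)
  removed$maf <- ids[bad]; keep <- keep & !bad

  mac <- pmin(alt, 2 * ncall - alt)
  bad <- keep & mac < thresholds$mac_min
  removed$mac <- ids[bad]; keep <- keep & !bad

  hwe_idx <- which(keep)
  hwe_p <- vapply(hwe_idx, function(j) hwe_p_column(d[, j]), 0)
  bad_hwe <- hwe_idx[hwe_p < thresholds$hwe_p_min]
  removed$hwe <- ids[bad_hwe]; keep[bad_hwe] <- FALSE

  out <- gt_subset(genotypes, variants = which(keep))
  report <- structure(list(
    axis = "variants",
    removed = removed,
    removed_counts = vapply(removed, length, 0L),
    n_input = ncol(d), n_retained = sum(keep),
    empty_result = sum(keep) == 0
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' Sample-level filtering on missingness
#'
#' Removes samples whose missing fraction strictly exceeds
#' `sample_missing_max`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` and `report`.
#' @export
filter_samples <- function(genotypes, thresholds = qc_thresholds()) {
  d <- genotypes$dosages
  stopifnot(nrow(d) >= 1)
  miss <- rowMeans(is.na(d))
  bad <- miss > thresholds$sample_missing_max
  out <- gt_subset(genotypes, samples = which(!bad))
  report <- structure(list(
    axis = "samples",
    removed = list(missingness = rownames(d)[bad]),
    removed_counts = c(missingness = sum(bad)),
    n_input = nrow(d), n_retained = sum(!bad),
    empty_result = all(bad)
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report (%s): %d -> %d\n", x$axis, x$n_input, x$n_retained))
  for (nm in names(x$removed_counts))
    cat(sprintf("  %-12s removed %d\n", nm, x$removed_counts[[nm]]))
  invisible(x)
}

#' Squared dosage correlation between two variants
#'
#' Pearson correlation squared over pairwise-complete samples.
#'
#' @param x,y dosage vectors.
#' @return r^2, or NA when undefined (fewer than two complete pairs, or zero
#'   variance in either variant).
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

# pairwise-complete squared Pearson correlation of one column against many
ld_r2_one_to_many <- function(x, Y) {
  xo <- !is.na(x)
  x0 <- ifelse(xo, x, 0)
  M <- (!is.na(Y)) & xo
  Y0 <- Y
  Y0[is.na(Y0)] <- 0
  n <- colSums(M)
  sx <- colSums(x0 * M)
  sy <- colSums(Y0 * M)
  sxx <- colSums(x0^2 * M)
  syy <- colSums(Y0^2 * M)
  sxy <- colSums(x0 * Y0 * M)
  num <- n * sxy - sx * sy
  den <- (n * sxx - sx^2) * (n * syy - sy^2)
  r2 <- ifelse(n >= 2 & den > 0, num^2 / den, NA_real_)
  r2
}

prune_window <- function(d, maf, active) {
  # greedy removal inside one window; returns updated logical `active`
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    r2 <- suppressWarnings(cor(d[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0
    mx <- max(r2)
    if (mx <= attr(active, "r2max")) break
    w <- which(r2 == mx, arr.ind = TRUE)[1, ]
    a <- idx[w[1]]; b <- idx[w[2]]
    # remove the lower-MAF member; tie -> later position (larger index)
    drop <- if (maf[a] < maf[b]) a
            else if (maf[b] < maf[a]) b
            else max(a, b)
    active[drop] <- FALSE
  }
  active
}

#' Windowed LD pruning
#'
#' Sliding window of `ld_window_bp` advanced by `ld_step_variants`; within a
#' window, while any retained pair has r^2 above `ld_r2_max`, the member with
#' lower MAF is removed (tie broken toward the later position). A final
#' verification sweep guarantees that no retained pair within the window span
#' exceeds the threshold.
#'
#' @param genotypes a [genotype_matrix()] (variants position-sorted).
#' @param thresholds a [qc_thresholds()].
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, thresholds = qc_thresholds()) {
  d <- genotypes$dosages
  vi <- genotypes$variant_info
  m <- ncol(d)
  if (m == 0) return(character(0))
  if (any(diff(order(vi$chrom, vi$pos)) != 1) &&
      !identical(order(vi$chrom, vi$pos), seq_len(m)))
    stop("variants must be position-sorted")
  maf <- vapply(seq_len(m), function(j) {
    ok <- !is.na(d[, j])
    if (!any(ok)) return(0)
    p <- sum(d[ok, j]) / (2 * sum(ok)); min(p, 1 - p)
  }, 0)
  keep <- rep(TRUE, m)
  attr(keep, "r2max") <- thresholds$ld_r2_max
  for (ch in unique(vi$chrom)) {
    on_ch <- which(vi$chrom == ch)
    s <- 1L
    while (s <= length(on_ch)) {
      j0 <- on_ch[s]
      in_win <- on_ch[vi$pos[on_ch] >= vi$pos[j0] &
                      vi$pos[on_ch] <= vi$pos[j0] + thresholds$ld_window_bp]
      act <- keep
      act[setdiff(seq_len(m), in_win)] <- FALSE
      attr(act, "r2max") <- thresholds$ld_r2_max
      act <- prune_window(d, maf, act)
      keep[in_win] <- act[in_win]
      s <- s + thresholds$ld_step_variants
    }
    # verification sweep: enforce the guarantee across window placements
    repeat {
      changed <- FALSE
      ret <- on_ch[keep[on_ch]]
      for (a in ret) {
        if (!keep[a]) next
        nb <- ret[keep[ret] & vi$pos[ret] > vi$pos[a] &
                    vi$pos[ret] - vi$pos[a] <= thresholds$ld_window_bp]
        if (!length(nb)) next
        r2 <- ld_r2_one_to_many(d[, a], d[, nb, drop = FALSE])
        for (b in nb[!is.na(r2) & r2 > thresholds$ld_r2_max]) {
          if (!keep[a] || !keep[b]) next
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b else max(a, b)
          keep[drop] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  vi$id[keep]
}

#' KING-robust kinship between two samples
#'
#' `phi = (N_het,het - 2 N_opposite-homozygote) / (N_het(x) + N_het(y))`
#' over shared non-missing variants. Exact duplicates give 0.5; unrelated
#' samples concentrate near 0.
#'
#' @param x,y dosage vectors for the two samples.
#' @param min_overlap minimum shared non-missing variants.
#' @return kinship estimate, or NA when the denominator is zero.
#' @export
king_kinship <- function(x, y, min_overlap = 50) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap)
    stop("fewer than ", min_overlap, " shared non-missing variants")
  x <- x[ok]; y <- y[ok]
  nhh <- sum(x == 1 & y == 1)
  nopp <- sum((x == 0 & y == 2) | (x == 2 & y == 0))
  denom <- sum(x == 1) + sum(y == 1)
  if (denom == 0) return(NA_real_)
  (nhh - 2 * nopp) / denom
}

#' All-pairs KING-robust kinship matrix
#'
#' Matrix-product formulation of [king_kinship()] for every sample pair.
#'
#' @param genotypes a [genotype_matrix()].
#' @param min_overlap pairs sharing fewer non-missing variants get NA.
#' @return symmetric n x n matrix, NA diagonal.
#' @export
kinship_matrix <- function(genotypes, min_overlap = 50) {
  d <- genotypes$dosages
  M <- (!is.na(d)) * 1
  H <- (!is.na(d) & d == 1) * 1
  A0 <- (!is.na(d) & d == 0) * 1
  A2 <- (!is.na(d) & d == 2) * 1
  nhh <- tcrossprod(H)
  nopp <- tcrossprod(A0, A2)
  nopp <- nopp + t(nopp)
  nh_shared <- tcrossprod(H, M)  # hets of row-sample over sites shared w/ col
  denom <- nh_shared + t(nh_shared)
  phi <- (nhh - 2 * nopp) / denom
  phi[denom == 0] <- NA
  shared <- tcrossprod(M)
  phi[shared < min_overlap] <- NA
  diag(phi) <- NA
  dimnames(phi) <- list(rownames(d), rownames(d))
  phi
}

#' Greedy relatedness removal
#'
#' While any retained pair exceeds `kinship_max`, drops the member involved
#' in more flagged pairs (ties broken toward the later sample).
#'
#' @param genotypes a [genotype_matrix()].
#' @param kinship_max kinship threshold (default third-degree cutoff).
#' @param min_overlap see [kinship_matrix()].
#' @return list with `retained` ids, `removed` ids, and the flagged `pairs`.
#' @export
remove_related <- function(genotypes, kinship_max = 0.0442,
                           min_overlap = 50) {
  phi <- kinship_matrix(genotypes, min_overlap)
  n <- nrow(phi)
  flag <- !is.na(phi) & phi > kinship_max
  ids <- rownames(phi)
  pr <- which(flag & upper.tri(flag), arr.ind = TRUE)
  pairs <- data.frame(sample1 = ids[pr[, 1]], sample2 = ids[pr[, 2]],
                      kinship = phi[pr], stringsAsFactors = FALSE)
  alive <- rep(TRUE, n)
  repeat {
    deg <- rowSums(flag[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    drop <- max(which(deg == max(deg)))  # tie -> later sample
    alive[drop] <- FALSE
    flag[drop, ] <- FALSE
    flag[, drop] <- FALSE
  }
  list(retained = ids[alive], removed = ids[!alive], pairs = pairs)
}
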