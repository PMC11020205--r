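#' Feature-selection configuration
#'
#' @param k_grid panel sizes evaluated (ascending).
#' @param rf_trees trees in the importance forest.
#' @param rf_max_split_features candidate features per split.
#' @param mrmr_prescreen candidate-pool size for the greedy mRMR search
#'   (top relevance), keeping the quadratic redundancy term tractable.
#' @param seed forest seed.
#' @return `fs_config` list.
#' @export
fs_config <- function(k_grid = c(5, 10, 15, 20, 50, 100, 200, 300, 500),
                      rf_trees = 500, rf_max_split_features = 35,
                      mrmr_prescreen = 500, seed = 1) {
  stopifnot(!is.unsorted(k_grid), rf_trees >= 1, rf_max_split_features >= 1)
  structure(as.list(environment()), class = "fs_config")
}

new_ranked_features <- function(method, ids, scores, fold = NA) {
  structure(data.frame(method = method, rank = seq_along(ids), id = ids,
                       score = scores, stringsAsFactors = FALSE),
            fold = fold, class = c("ranked_features", "data.frame"))
}

#' Rank variants by association statistics
#'
#' Ascending p; ties broken by descending `|beta|`, then identifier;
#' non-converged variants rank last.
#'
#' @param stats a `summary_stats` data.frame.
#' @param fold optional fold id recorded on the ranking.
#' @return `ranked_features` data.frame with the p-value as score.
#' @export
rank_by_gwas <- function(stats, fold = NA) {
  stopifnot(nrow(stats) > 0)
  ab <- ifelse(is.na(stats$beta), 0, abs(stats$beta))
  o <- order(!stats$converged, stats$p, -ab, stats$id)
  new_ranked_features("gwas", stats$id[o], stats$p[o], fold)
}

mi_pair <- function(xi, yi, nx, ny) {
  # xi in 0..(nx-1), yi in 0..(ny-1), complete cases, integer-coded
  n <- length(xi)
  if (n <= 1) return(0)
  joint <- tabulate(xi * ny + yi + 1L, nx * ny) / n
  px <- tabulate(xi + 1L, nx) / n
  py <- tabulate(yi + 1L, ny) / n
  pp <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / t(pp)[nz]))
}

#' Plug-in mutual information between a genotype and a binary status
#'
#' `I = sum p(x,y) log[p(x,y) / (p(x) p(y))]` in nats over observed cells,
#' complete cases only, no pseudocounts. A single complete pair returns 0 by
#' convention, flagged via attribute `degenerate`.
#'
#' @param x genotype vector (categories 0/1/2, NA allowed).
#' @param y second discrete vector (binary status, or another genotype).
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stopifnot(sum(ok) >= 1)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 1)
    return(structure(0, degenerate = TRUE))
  ux <- sort(unique(x)); uy <- sort(unique(y))
  mi_pair(match(x, ux) - 1L, match(y, uy) - 1L, length(ux), length(uy))
}

mi_columns <- function(G, y) {
  # MI of each integer-coded genotype column (0/1/2) with binary y
  yi <- as.integer(y)
  vapply(seq_len(ncol(G)), function(j) mi_pair(G[, j], yi, 3L, 2L), 0)
}

#' Greedy minimum-redundancy maximum-relevance selection
#'
#' Difference criterion: the first pick maximizes relevance `I(x; y)`;
#' subsequent picks maximize `I(x; y) - mean_{s in S} I(x; s)`. Ties break
#' toward larger relevance, then identifier. Missing calls are replaced by
#' the rounded per-variant mean so genotypes stay categorical.
#'
#' @param genotypes a [genotype_matrix()].
#' @param status binary phenotype vector.
#' @param k panel size.
#' @param candidates optional variant ids restricting the pool (pre-reduced
#'   post-QC/pruning candidates).
#' @param fold optional fold id.
#' @return `ranked_features` with the greedy adjusted score at pick time.
#' @export
mrmr_select <- function(genotypes, status, k, candidates = NULL, fold = NA) {
  d <- genotypes$dosages
  ids <- genotypes$variant_info$id
  if (!is.null(candidates)) {
    j <- match(candidates, ids)
    d <- d[, j, drop = FALSE]; ids <- ids[j]
  }
  if (k > ncol(d)) stop("k exceeds candidate count")
  G <- d
  if (anyNA(G)) {
    mm <- round(colMeans(G, na.rm = TRUE))
    idx <- which(is.na(G))
    G[idx] <- mm[((idx - 1L) %/% nrow(G)) + 1L]
  }
  storage.mode(G) <- "integer"
  rel <- mi_columns(G, status)
  m <- ncol(G)
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(m)
  remaining <- rep(TRUE, m)
  for (step in seq_len(k)) {
    adj <- if (length(selected) == 0) rel
           else rel - red_sum / length(selected)
    adj[!remaining] <- -Inf
    best <- max(adj)
    cand <- which(adj == best)
    if (length(cand) > 1) {
      cand <- cand[rel[cand] == max(rel[cand])]
      cand <- cand[order(ids[cand])][1]
    }
    selected <- c(selected, cand)
    scores <- c(scores, best)
    remaining[cand] <- FALSE
    if (step < k) {
      xi <- G[, cand]
      upd <- which(remaining)
      red_sum[upd] <- red_sum[upd] +
        vapply(upd, function(j) mi_pair(G[, j], xi, 3L, 3L), 0)
    }
  }
  new_ranked_features("mrmr", ids[selected], scores, fold)
}

#' Random-forest importance ranking
#'
#' Impurity-decrease importances from a classification forest (default 500
#' trees, 35 candidate features per split); descending importance, ties by
#' identifier; deterministic given the seed. Missing dosages are mean-imputed
#' per variant.
#'
#' @param genotypes a [genotype_matrix()].
#' @param status binary phenotype vector.
#' @param config an [fs_config()].
#' @param fold optional fold id.
#' @return `ranked_features` with the importance as score.
#' @export
rf_importance_rank <- function(genotypes, status, config = fs_config(),
                               fold = NA) {
  if (length(unique(status)) < 2) stop("degenerate single-class status")
  G <- impute_mean(genotypes$dosages)$imputed
  colnames(G) <- genotypes$variant_info$id
  fit <- ranger::ranger(
    x = G, y = factor(status), num.trees = config$rf_trees,
    mtry = min(config$rf_max_split_features, ncol(G)),
    importance = "impurity", seed = config$seed, num.threads = 1,
    verbose = FALSE)
  imp <- fit$variable.importance
  o <- order(-imp, names(imp))
  new_ranked_features("rf", names(imp)[o], unname(imp[o]), fold)
}

#' Take the top-k identifiers from a ranking
#'
#' @param ranked a `ranked_features` data.frame.
#' @param k panel size (0 allowed).
#' @return character vector of the first `k` identifiers.
#' @export
select_top_k <- function(ranked, k) {
  if (k > nrow(ranked)) stop("k exceeds ranking length")
  head(ranked$id, k)
}
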