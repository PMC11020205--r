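#' Run code with a private RNG stream
#'
#' Evaluates `expr` after seeding the RNG with `seed`, restoring the caller's
#' RNG state on exit so library internals never perturb user-level streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed
#'
#' Deterministic, stays below 2^31 so it is always a valid R integer seed.
#'
#' @param seed parent seed.
#' @param k stream index.
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 104729) %% 2147483629)
}

#' Construct a genotype matrix container
#'
#' @param dosages integer matrix, samples x variants, values 0/1/2 or NA for
#'   missing; rownames are sample ids, colnames variant ids.
#' @param variant_info data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per variant, aligned to `dosages` columns.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variant_info) {
  stopifnot(is.matrix(dosages), nrow(variant_info) == ncol(dosages))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  colnames(dosages) <- variant_info$id
  for (ch in unique(variant_info$chrom)) {
    p <- variant_info$pos[variant_info$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome")
  }
  structure(list(dosages = dosages, variant_info = variant_info),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param gt genotype_matrix.
#' @param samples row index (ids, logical or integer); NULL keeps all.
#' @param variants column index; NULL keeps all.
#' @return genotype_matrix.
#' @export
gt_subset <- function(gt, samples = NULL, variants = NULL) {
  d <- gt$dosages
  vi <- gt$variant_info
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, vi$id)
    d <- d[, variants, drop = FALSE]
    vi <- vi[variants, , drop = FALSE]
  }
  rownames(vi) <- NULL
  genotype_matrix(d, vi)
}

#' Per-variant mean imputation of missing dosages
#'
#' Means may be supplied (e.g. learned on a training fold) so held-out data
#' is imputed without touching its own distribution.
#'
#' @param dosages numeric matrix with NA for missing.
#' @param means optional per-column means; computed from `dosages` if NULL.
#' @return list with `imputed` matrix and the `means` used.
#' @export
impute_mean <- function(dosages, means = NULL) {
  if (is.null(means)) {
    means <- colMeans(dosages, na.rm = TRUE)
    means[is.nan(means)] <- 0
  }
  idx <- which(is.na(dosages))
  if (length(idx)) {
    cols <- ((idx - 1L) %/% nrow(dosages)) + 1L
    dosages[idx] <- means[cols]
  }
  list(imputed = dosages, means = means)
}
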