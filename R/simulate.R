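#' Default clinical risk-factor specification
#'
#' Marginal distributions emulate baseline characteristics typical of a large
#' middle-aged European cohort: age in years, binary sex (1 = male), BMI in
#' kg/m^2, LDL/HDL/triglycerides in mmol/L, systolic blood pressure in mmHg,
#' binary smoking and diabetes status, and categorical genotyping batch and
#' assessment centre (no liability effect). `beta` is the effect of the
#' standardized covariate on the liability scale.
#'
#' @return list of covariate definitions.
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "age",      dist = "gaussian",  mean = 56.5, sd = 8.1,  beta = 0.15),
    list(name = "sex",      dist = "bernoulli", p = 0.456,              beta = 0.15),
    list(name = "bmi",      dist = "gaussian",  mean = 27.4, sd = 4.8,  beta = 0.10),
    list(name = "ldl",      dist = "gaussian",  mean = 3.6,  sd = 0.9,  beta = 0.10),
    list(name = "hdl",      dist = "gaussian",  mean = 1.4,  sd = 0.4,  beta = -0.10),
    list(name = "trig",     dist = "gaussian",  mean = 1.7,  sd = 1.0,  beta = 0.08),
    list(name = "sbp",      dist = "gaussian",  mean = 139.7, sd = 19.7, beta = 0.10),
    list(name = "smoking",  dist = "bernoulli", p = 0.455,              beta = 0.10),
    list(name = "diabetes", dist = "bernoulli", p = 0.056,              beta = 0.08),
    list(name = "batch",    dist = "categorical", k = 5,                beta = 0),
    list(name = "center",   dist = "categorical", k = 10,               beta = 0)
  )
}

# Latent (Gaussian-copula) correlations among risk factors; pairs not listed
# are independent. Kept modest so the matrix is comfortably positive definite.
default_covariate_corr_pairs <- function() {
  list(
    c("age", "sbp", 0.30),
    c("bmi", "trig", 0.30),
    c("bmi", "hdl", -0.25),
    c("bmi", "sbp", 0.20),
    c("bmi", "diabetes", 0.30),
    c("hdl", "trig", -0.40),
    c("ldl", "trig", 0.20),
    c("smoking", "hdl", -0.10)
  )
}

#' Simulation configuration
#'
#' @param n_samples number of individuals.
#' @param n_variants number of biallelic SNPs.
#' @param n_blocks number of LD blocks (variants split near-evenly).
#' @param within_block_corr latent AR(1) correlation between adjacent
#'   variants on the same haplotype within a block, in `[0, 1)`.
#' @param maf_range range of ancestral allele frequencies, within `(0, 0.5]`.
#' @param n_subpops number of subpopulations.
#' @param fst Balding-Nichols divergence parameter, in `[0, 0.5)`.
#' @param n_causal number of planted causal variants.
#' @param h2_liability liability variance explained by planted variants.
#' @param prevalence disease prevalence on the liability scale.
#' @param covariate_spec list of covariate definitions
#'   (see [default_covariate_spec()]).
#' @param covariate_corr_pairs list of `(name1, name2, rho)` latent
#'   correlations.
#' @param missing_rate per-call missingness probability.
#' @param n_duplicate_pairs duplicated samples appended for kinship testing.
#' @param bp_per_block physical span of each LD block in base pairs.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 2000, n_variants = 2000, n_blocks = 100,
                       within_block_corr = 0.8, maf_range = c(0.05, 0.5),
                       n_subpops = 2, fst = 0.02, n_causal = 20,
                       h2_liability = 0.5, prevalence = 0.3,
                       covariate_spec = default_covariate_spec(),
                       covariate_corr_pairs = default_covariate_corr_pairs(),
                       missing_rate = 0.02, n_duplicate_pairs = 0,
                       bp_per_block = 100000, seed = 1) {
  stopifnot(n_samples >= 1, n_variants >= 1, n_blocks >= 1,
            within_block_corr >= 0, within_block_corr < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_subpops >= 1, fst >= 0, fst < 0.5,
            n_causal >= 0, n_causal <= n_variants,
            h2_liability >= 0, h2_liability <= 1,
            prevalence > 0, prevalence < 1,
            missing_rate >= 0, missing_rate < 1,
            n_duplicate_pairs >= 0, n_duplicate_pairs <= n_samples / 2,
            bp_per_block >= n_variants / n_blocks + 1)
  if (n_blocks > n_variants)
    stop("n_blocks exceeds n_variants: block assignment would be empty")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

block_assignment <- function(n_variants, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n_variants))
}

#' Simulate genotypes with block LD and population structure
#'
#' Ancestral allele frequencies are drawn uniformly from `maf_range`;
#' subpopulation frequencies follow the Balding-Nichols model
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. Within each block, haplotype alleles are
#' obtained by thresholding a latent AR(1) Gaussian at the subpopulation
#' frequency quantile, giving tunable adjacent-variant correlation while
#' preserving marginal frequencies; blocks are mutually independent. Two
#' haplotypes sum to the additive dosage.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (list
#'   with `subpop_labels`, per-subpop allele frequencies, block ids).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples; m <- config$n_variants
  K <- config$n_subpops; F <- config$fst
  with_seed(child_seed(config$seed, 1), {
    p0 <- runif(m, config$maf_range[1], config$maf_range[2])
    pk <- matrix(p0, nrow = K, ncol = m, byrow = TRUE)
    if (F > 0 && K > 1) {
      a <- p0 * (1 - F) / F
      b <- (1 - p0) * (1 - F) / F
      for (k in seq_len(K))
        pk[k, ] <- stats::rbeta(m, a, b)
      pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
    }
    subpop <- rep_len(seq_len(K), n)
    blocks <- block_assignment(m, config$n_blocks)
    rho <- config$within_block_corr
    dos <- matrix(0L, n, m)
    # two latent haplotype fields per sample, AR(1) within block
    for (h in 1:2) {
      z <- matrix(rnorm(n * m), n, m)
      if (rho > 0) {
        w <- sqrt(1 - rho^2)
        for (j in 2:m) if (blocks[j] == blocks[j - 1])
          z[, j] <- rho * z[, j - 1] + w * z[, j]
      }
      thr <- qnorm(t(pk)[cbind(rep(seq_len(m), each = n), rep(subpop, m))])
      allele <- z < matrix(thr, n, m)
      dos <- dos + allele
    }
    storage.mode(dos) <- "integer"
  })
  per_block <- tabulate(block_assignment(m, config$n_blocks), config$n_blocks)
  pos <- integer(m); i <- 1L
  for (b in seq_len(config$n_blocks)) {
    len <- per_block[b]
    step <- config$bp_per_block %/% (len + 1L)
    pos[i:(i + len - 1L)] <-
      as.integer((b - 1) * config$bp_per_block) + step * seq_len(len)
    i <- i + len
  }
  vi <- data.frame(id = sprintf("snp%05d", seq_len(m)), chrom = "1",
                   pos = as.integer(pos), ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  rownames(dos) <- sprintf("S%05d", seq_len(n))
  gt <- genotype_matrix(dos, vi)
  truth <- list(subpop_labels = rep_len(seq_len(K), n),
                subpop_freqs = pk, ancestral_freqs = p0,
                block_ids = block_assignment(m, config$n_blocks))
  list(genotypes = gt, truth = truth)
}

#' Simulate clinical risk factors and covariates
#'
#' Continuous covariates are Gaussian, binary ones Bernoulli via a Gaussian
#' copula carrying the configured latent correlations, categorical ones
#' uniform and independent. The standardized liability contribution
#' `sum(beta_c * z_c)` is attached as attribute `"liability"`.
#'
#' @param config a [sim_config()].
#' @param n_samples overrides `config$n_samples` when given.
#' @return data.frame with `sample_id` first, one column per covariate.
#' @export
simulate_risk_factors <- function(config, n_samples = NULL) {
  n <- if (is.null(n_samples)) config$n_samples else n_samples
  spec <- config$covariate_spec
  nm <- vapply(spec, `[[`, "", "name")
  dist <- vapply(spec, `[[`, "", "dist")
  bad <- setdiff(dist, c("gaussian", "bernoulli", "categorical"))
  if (length(bad)) stop("unknown distribution name: ", paste(bad, collapse = ", "))
  cop <- which(dist != "categorical")
  R <- diag(length(cop))
  dimnames(R) <- list(nm[cop], nm[cop])
  for (pr in config$covariate_corr_pairs) {
    a <- pr[[1]]; b <- pr[[2]]; r <- as.numeric(pr[[3]])
    if (a %in% rownames(R) && b %in% rownames(R)) {
      R[a, b] <- r; R[b, a] <- r
    }
  }
  out <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  liab <- numeric(n)
  with_seed(child_seed(config$seed, 2), {
    Z <- matrix(rnorm(n * length(cop)), n) %*% chol(R)
    colnames(Z) <- nm[cop]
    for (s in spec) {
      if (s$dist == "gaussian") {
        z <- Z[, s$name]
        out[[s$name]] <- s$mean + s$sd * z
        liab <- liab + s$beta * z
      } else if (s$dist == "bernoulli") {
        z <- Z[, s$name]
        x <- as.integer(z < qnorm(s$p))
        out[[s$name]] <- x
        liab <- liab + s$beta * (x - s$p) / sqrt(s$p * (1 - s$p))
      } else {
        if (!is.null(s$beta) && s$beta != 0)
          stop("categorical covariates cannot carry a liability effect")
        out[[s$name]] <- sample.int(s$k, n, replace = TRUE)
      }
    }
  })
  attr(out, "liability") <- liab
  out
}

#' Simulate a binary phenotype under the liability-threshold model
#'
#' Planted causal variants get equal-magnitude, random-sign effects on
#' standardized dosages, rescaled so the realized genetic liability variance
#' equals `h2_liability` exactly. Liability = genetic + covariate + Gaussian
#' residual (total variance 1); disease status is 1 when liability exceeds
#' the `1 - prevalence` Gaussian quantile.
#'
#' @param genotypes a [genotype_matrix()] (complete calls).
#' @param truth truth list from [simulate_genotypes()].
#' @param covariates data.frame from [simulate_risk_factors()].
#' @param config a [sim_config()].
#' @return list with `phenotypes` (data.frame: sample_id, status, covariates)
#'   and updated `truth` (causal ids/betas, liability).
#' @export
simulate_phenotype <- function(genotypes, truth, covariates, config) {
  n <- nrow(genotypes$dosages)
  cvl <- attr(covariates, "liability")
  if (is.null(cvl)) cvl <- numeric(n)
  var_c <- if (n > 1) var(cvl) else 0
  if (config$h2_liability + var_c > 1)
    stop("liability variance budget exceeded: h2 + covariate variance > 1")
  with_seed(child_seed(config$seed, 3), {
    if (config$n_causal > 0) {
      causal <- sort(sample.int(ncol(genotypes$dosages), config$n_causal))
      Zc <- scale(genotypes$dosages[, causal, drop = FALSE])
      Zc[is.na(Zc)] <- 0
      beta <- sqrt(config$h2_liability / config$n_causal) *
        sample(c(-1, 1), config$n_causal, replace = TRUE)
      g <- drop(Zc %*% beta)
      sg <- sd(g)
      if (sg > 0) {
        adj <- sqrt(config$h2_liability) / sg
        g <- g * adj
        beta <- beta * adj
      }
    } else {
      causal <- integer(0); beta <- numeric(0); g <- numeric(n)
    }
    res_var <- max(1 - config$h2_liability - var_c, 0)
    liab <- g + cvl + rnorm(n, 0, sqrt(res_var))
  })
  status <- as.integer(liab > qnorm(1 - config$prevalence))
  ph <- data.frame(sample_id = rownames(genotypes$dosages),
                   status = status, stringsAsFactors = FALSE)
  ph <- cbind(ph, covariates[, setdiff(names(covariates), "sample_id"),
                             drop = FALSE])
  truth$causal_ids <- genotypes$variant_info$id[causal]
  truth$causal_betas <- beta
  truth$liability <- liab
  # noise-free part: the ceiling any predictor of status can reach
  truth$liability_expected <- g + cvl
  list(phenotypes = ph, truth = truth)
}

#' Set dosages to missing at random
#'
#' @param genotypes a [genotype_matrix()].
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param seed RNG seed.
#' @param variants optional variant ids/indices: mask only these columns.
#' @return genotype_matrix with NAs injected.
#' @export
inject_missingness <- function(genotypes, missing_rate, seed,
                               variants = NULL) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0) return(genotypes)
  d <- genotypes$dosages
  cols <- if (is.null(variants)) seq_len(ncol(d))
          else if (is.character(variants)) match(variants, genotypes$variant_info$id)
          else variants
  with_seed(seed, {
    mask <- matrix(runif(nrow(d) * length(cols)) < missing_rate,
                   nrow(d), length(cols))
    d[, cols][mask] <- NA
  })
  genotype_matrix(d, genotypes$variant_info)
}

#' Append exact-duplicate samples
#'
#' Creates planted positives for the kinship filter: a duplicated sample has
#' KING-robust kinship exactly 0.5 with its source.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n_duplicate_pairs number of samples to copy.
#' @param seed RNG seed.
#' @return list with `genotypes` (rows appended) and `pairs` data.frame
#'   (`source`, `duplicate` sample ids).
#' @export
spike_relatedness <- function(genotypes, n_duplicate_pairs, seed) {
  n <- nrow(genotypes$dosages)
  stopifnot(n_duplicate_pairs <= n / 2)
  if (n_duplicate_pairs == 0)
    return(list(genotypes = genotypes,
                pairs = data.frame(source = character(0),
                                   duplicate = character(0))))
  src <- with_seed(seed, sample.int(n, n_duplicate_pairs))
  d <- genotypes$dosages
  dup <- d[src, , drop = FALSE]
  rownames(dup) <- paste0(rownames(d)[src], "_dup")
  out <- genotype_matrix(rbind(d, dup), genotypes$variant_info)
  list(genotypes = out,
       pairs = data.frame(source = rownames(d)[src],
                          duplicate = rownames(dup),
                          stringsAsFactors = FALSE))
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: genotypes, risk factors, liability-threshold
#' phenotype, then optional missingness and duplicate spiking. Duplicated
#' samples reuse their source's phenotype row.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `phenotypes`, `truth`, `pairs`, `config`.
#' @export
simulate_cohort <- function(config) {
  sg <- simulate_genotypes(config)
  rf <- simulate_risk_factors(config)
  sp <- simulate_phenotype(sg$genotypes, sg$truth, rf, config)
  gt <- sg$genotypes
  ph <- sp$phenotypes
  if (config$missing_rate > 0)
    gt <- inject_missingness(gt, config$missing_rate,
                             child_seed(config$seed, 4))
  pairs <- data.frame(source = character(0), duplicate = character(0))
  if (config$n_duplicate_pairs > 0) {
    sr <- spike_relatedness(gt, config$n_duplicate_pairs,
                            child_seed(config$seed, 5))
    gt <- sr$genotypes
    pairs <- sr$pairs
    extra <- ph[match(pairs$source, ph$sample_id), , drop = FALSE]
    extra$sample_id <- pairs$duplicate
    ph <- rbind(ph, extra)
    rownames(ph) <- NULL
  }
  list(genotypes = gt, phenotypes = ph, truth = sp$truth,
       pairs = pairs, config = config)
}
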