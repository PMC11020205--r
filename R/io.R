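#' Write a genotype matrix as VCF v4.2 (GT only)
#'
#' Hard calls, missing as `./.`, 1-based positions.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  vi <- genotypes$variant_info
  d <- genotypes$dosages
  hdr <- c("##fileformat=VCFv4.2",
           "##source=prsfs",
           paste0("##contig=<ID=", unique(vi$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  if (nrow(vi) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  code <- c("0/0", "0/1", "1/1")
  g <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  g[ok] <- code[d[ok] + 1L]
  body <- vapply(seq_len(nrow(vi)), function(j) {
    paste(c(vi$chrom[j], vi$pos[j], vi$id[j], vi$ref[j], vi$alt[j],
            ".", "PASS", ".", "GT", g[, j]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF with GT calls into a genotype matrix
#'
#' Biallelic hard calls only; `./.` becomes NA. Phased separators are
#' accepted.
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  chrom_line <- grep("^#CHROM", lines, value = TRUE)
  if (length(chrom_line) != 1) stop("malformed VCF: missing #CHROM header")
  fields <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  samples <- if (length(fields) > 9) fields[-(1:9)] else character(0)
  n_records <- sum(!startsWith(lines, "#"))
  if (n_records == 0) {
    d <- matrix(integer(0), nrow = length(samples), ncol = 0)
    rownames(d) <- samples
    vi <- data.frame(id = character(0), chrom = character(0),
                     pos = integer(0), ref = character(0),
                     alt = character(0), stringsAsFactors = FALSE)
    return(genotype_matrix(d, vi))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  vi <- data.frame(id = vcfR::getID(v), chrom = vcfR::getCHROM(v),
                   pos = as.integer(vcfR::getPOS(v)),
                   ref = vcfR::getREF(v), alt = vcfR::getALT(v),
                   stringsAsFactors = FALSE)
  gt2 <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt2), ncol(gt2))
  dos[gt2 == "0/0"] <- 0L
  dos[gt2 %in% c("0/1", "1/0")] <- 1L
  dos[gt2 == "1/1"] <- 2L
  bad <- !is.na(gt2) & gt2 != "./." & is.na(dos)
  if (any(bad)) stop("malformed VCF GT field: ", gt2[bad][1])
  d <- t(dos)
  rownames(d) <- colnames(gt)
  genotype_matrix(d, vi)
}

#' Write a cohort to disk
#'
#' VCF for genotypes, TSV (header, `sample_id` first) for phenotypes and
#' covariates, JSON sidecar for simulation ground truth if supplied.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype/covariate data.frame.
#' @param path output directory (created if needed).
#' @param truth optional ground-truth list.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(genotypes, phenotypes, path, truth = NULL) {
  if (!identical(sort(rownames(genotypes$dosages)),
                 sort(phenotypes$sample_id)))
    stop("sample mismatch between genotypes and phenotypes")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_vcf(genotypes, file.path(path, "genotypes.vcf"))
  write.table(phenotypes, file.path(path, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    tr <- truth
    tr$subpop_freqs <- NULL  # matrix-valued; not round-tripped
    jsonlite::write_json(tr, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cohort from disk
#'
#' @param path directory written by [write_dataset()].
#' @return list with `genotypes`, `phenotypes` and `truth` (NULL if absent).
#' @export
read_dataset <- function(path) {
  gt <- read_vcf(file.path(path, "genotypes.vcf"))
  ph <- read.delim(file.path(path, "phenotypes.tsv"), sep = "\t",
                   stringsAsFactors = FALSE)
  if (!identical(sort(rownames(gt$dosages)), sort(ph$sample_id)))
    stop("sample mismatch between genotypes.vcf and phenotypes.tsv")
  ph <- ph[match(rownames(gt$dosages), ph$sample_id), , drop = FALSE]
  rownames(ph) <- NULL
  tr_path <- file.path(path, "truth.json")
  truth <- if (file.exists(tr_path))
    jsonlite::read_json(tr_path, simplifyVector = TRUE) else NULL
  list(genotypes = gt, phenotypes = ph, truth = truth)
}
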