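#' Build a synthetic LD-structured haplotype pool
#'
#' Generates a pool of phased binary haplotypes with block-like linkage
#' disequilibrium, a synthetic stand-in for a region of a reference panel
#' such as the 1000 Genomes EUR haplotypes.  Haplotypes are produced by a
#' first-order Markov copying process along the SNPs: each SNP carries a
#' latent uniform variate that is either copied from the previous SNP
#' (probability `ld_decay`) or drawn fresh, and the allele is the indicator
#' that the latent variate falls below the SNP's target allele frequency.
#' Copying induces positive correlation between adjacent SNPs of roughly
#' `ld_decay` (attenuated when their allele frequencies differ), while the
#' thresholding guarantees each SNP's marginal frequency equals its target.
#'
#' @param n_hap Number of haplotypes (rows), at least 2.
#' @param n_snp Number of SNPs (columns), at least 1.
#' @param ld_decay Copying probability in `[0, 1)`; 0 gives independent SNPs,
#'   values near 1 give long stretches of near-perfect LD.
#' @param maf_range Length-2 numeric, lower and upper bound of the per-SNP
#'   target minor allele frequency; `0 < low <= high < 1`.
#' @param seed Integer seed; the pool is bit-reproducible given the seed.
#'
#' @return An object of class `haplotype_pool`: a list with `haplotypes`
#'   (0/1 matrix, `n_hap` x `n_snp`), `snp_ids`, `positions` (strictly
#'   increasing bp), and `allele_freq` (column means).
#' @examples
#' pool <- build_haplotype_pool(200, 50, ld_decay = 0.9, seed = 1)
#' range(pool$allele_freq)
#' @export
build_haplotype_pool <- function(n_hap, n_snp, ld_decay = 0.9,
                                 maf_range = c(0.05, 0.5), seed = 1L) {
  if (length(n_hap) != 1L || n_hap < 2L) stop("n_hap must be >= 2")
  if (length(n_snp) != 1L || n_snp < 1L) stop("n_snp must be >= 1")
  if (!is.numeric(ld_decay) || ld_decay < 0 || ld_decay >= 1)
    stop("ld_decay must be in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < low <= high < 1")
  set.seed(as.integer(seed))
  freq <- stats::runif(n_snp, maf_range[1], maf_range[2])
  # latent uniforms: copy previous with prob ld_decay, else redraw
  u <- matrix(stats::runif(n_hap * n_snp), n_hap, n_snp)
  if (n_snp > 1L && ld_decay > 0) {
    copy <- matrix(stats::runif(n_hap * (n_snp - 1L)) < ld_decay,
                   n_hap, n_snp - 1L)
    for (j in 2:n_snp) {
      cj <- copy[, j - 1L]
      u[cj, j] <- u[cj, j - 1L]
    }
  }
  hap <- matrix(0L, n_hap, n_snp)
  hap[sweep(u, 2L, freq, "<")] <- 1L
  pool <- structure(list(
    haplotypes  = hap,
    snp_ids     = sprintf("snp%04d", seq_len(n_snp)),
    positions   = seq_len(n_snp) * 1000L,
    allele_freq = colMeans(hap)
  ), class = "haplotype_pool")
  validate_haplotype_pool(pool)
}

validate_haplotype_pool <- function(pool) {
  h <- pool$haplotypes
  if (!all(h %in% c(0L, 1L))) stop("haplotypes must be 0/1")
  if (is.unsorted(pool$positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (length(pool$snp_ids) != ncol(h) || length(pool$positions) != ncol(h))
    stop("snp_ids/positions length must match SNP count")
  pool$allele_freq <- colMeans(h)
  pool
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("<haplotype_pool> %d haplotypes x %d SNPs, MAF in [%.3f, %.3f]\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              min(pmin(x$allele_freq, 1 - x$allele_freq)),
              max(pmin(x$allele_freq, 1 - x$allele_freq))))
  invisible(x)
}

#' Sample diplotype individuals from a haplotype pool
#'
#' Each individual is formed by drawing two haplotypes uniformly with
#' replacement from the pool and summing them into an additive dosage
#' vector, mimicking sampling pairs of reference haplotypes to build a
#' genotype data set.
#'
#' @param pool A [build_haplotype_pool()] / [load_haplotypes()] object.
#' @param n_ind Number of individuals to sample (> 0).
#' @param seed Integer seed.
#' @return An object of class `genotype_matrix`: list with `dosages`
#'   (`n_ind` x `n_snp` integer matrix in 0/1/2), `individual_ids`,
#'   `snp_ids`, `positions`.
#' @export
sample_genotypes <- function(pool, n_ind, seed = 1L) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (length(n_ind) != 1L || n_ind <= 0L) stop("n_ind must be positive")
  set.seed(as.integer(seed))
  n_hap <- nrow(pool$haplotypes)
  i1 <- sample.int(n_hap, n_ind, replace = TRUE)
  i2 <- sample.int(n_hap, n_ind, replace = TRUE)
  dos <- pool$haplotypes[i1, , drop = FALSE] + pool$haplotypes[i2, , drop = FALSE]
  storage.mode(dos) <- "integer"
  structure(list(
    dosages        = dos,
    individual_ids = sprintf("ind%05d", seq_len(n_ind)),
    snp_ids        = pool$snp_ids,
    positions      = pool$positions
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Load a haplotype pool from a phased VCF or a plain haplotype matrix
#'
#' VCF input must contain phased, biallelic genotypes (`0|1` style GT);
#' unphased or multi-allelic records are rejected.  The plain-matrix format
#' is a TSV with one row per haplotype and a header of SNP ids, optionally
#' accompanied by a SNP map (`map_path`, TSV with columns `snp_id` and
#' `position`); without a map, positions default to the column index.
#'
#' @param path File to read.
#' @param format `"vcf"` or `"matrix"`.
#' @param map_path Optional SNP map for `format = "matrix"`.
#' @return A `haplotype_pool`.
#' @export
load_haplotypes <- function(path, format = c("vcf", "matrix"), map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") load_haplotypes_vcf(path) else
    load_haplotypes_matrix(path, map_path)
}

load_haplotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) stop("missing or non-numeric POS in VCF")
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic records are not supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || !ncol(gt)) stop("VCF has no sample GT columns")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype encountered")
  if (anyNA(gt)) stop("missing genotypes are not supported")
  # gt is variants x samples of "a|b" strings
  split_al <- strsplit(as.vector(t(gt)), "|", fixed = TRUE)
  if (any(lengths(split_al) != 2L)) stop("GT is not diploid phased")
  al <- suppressWarnings(as.integer(unlist(split_al)))
  if (anyNA(al) || any(al > 1L)) stop("missing or non-biallelic allele in GT")
  n_snp <- nrow(gt); n_sam <- ncol(gt)
  # unlist order: variant-major over samples, two alleles per sample
  hap <- matrix(al, nrow = 2L * n_sam, ncol = n_snp)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("snp%04d", which(is.na(ids) | ids == "."))
  ord <- order(pos)
  pool <- structure(list(
    haplotypes  = hap[, ord, drop = FALSE],
    snp_ids     = unname(ids[ord]),
    positions   = pos[ord],
    allele_freq = colMeans(hap[, ord, drop = FALSE])
  ), class = "haplotype_pool")
  validate_haplotype_pool(pool)
}

load_haplotypes_matrix <- function(path, map_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  hap <- as.matrix(tab)
  storage.mode(hap) <- "integer"
  snp_ids <- colnames(hap)
  positions <- seq_len(ncol(hap)) * 1L
  if (!is.null(map_path)) {
    map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("snp_id", "position") %in% names(map)))
      stop("SNP map needs columns snp_id and position")
    m <- match(snp_ids, map$snp_id)
    if (anyNA(m)) stop("SNP map is missing positions for some SNPs")
    positions <- as.integer(map$position[m])
  }
  pool <- structure(list(haplotypes = hap, snp_ids = snp_ids,
                         positions = positions,
                         allele_freq = colMeans(hap)),
                    class = "haplotype_pool")
  validate_haplotype_pool(pool)
}

#' Write a haplotype pool as a plain TSV matrix (+ SNP map)
#'
#' @param pool A `haplotype_pool`.
#' @param path Output TSV (rows = haplotypes, header = SNP ids).
#' @param map_path Optional path for the SNP map TSV.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(pool, path, map_path = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"))
  tab <- as.data.frame(pool$haplotypes)
  names(tab) <- pool$snp_ids
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path)) {
    utils::write.table(
      data.frame(snp_id = pool$snp_ids, position = pool$positions),
      map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Pairwise LD (squared Pearson correlation) between dosage columns
#'
#' @param geno A `genotype_matrix` (or plain dosage matrix).
#' @param snp_subset Optional integer/logical/character index of SNPs.
#' @return A symmetric matrix of squared correlations with unit diagonal;
#'   rows/columns of monomorphic SNPs are `NA` and flagged via the
#'   `monomorphic` attribute (logical vector).
#' @export
ld_r2_matrix <- function(geno, snp_subset = NULL) {
  dos <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  if (nrow(dos) < 2L) stop("need at least 2 individuals")
  if (!is.null(snp_subset)) dos <- dos[, snp_subset, drop = FALSE]
  v <- apply(dos, 2L, stats::var)
  mono <- v == 0 | is.na(v)
  r2 <- matrix(NA_real_, ncol(dos), ncol(dos))
  if (any(!mono)) {
    cc <- suppressWarnings(stats::cor(dos[, !mono, drop = FALSE]))
    r2[!mono, !mono] <- cc^2
  }
  diag(r2)[!mono] <- 1
  dimnames(r2) <- list(colnames(dos), colnames(dos))
  attr(r2, "monomorphic") <- mono
  r2
}
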