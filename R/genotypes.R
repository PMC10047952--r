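#' Simulate independent biallelic genotypes in Hardy-Weinberg proportions
#'
#' Each SNP gets a minor-allele frequency drawn uniformly in
#' `[maf_low, maf_high]`; additive dosages (minor-allele counts 0/1/2) are
#' drawn per subject as Binomial(2, maf), i.e. Hardy-Weinberg equilibrium
#' with no linkage disequilibrium between SNPs. SNPs are assigned to
#' chromosomes 1..22 round-robin with monotonically increasing base-pair
#' positions within each chromosome.
#'
#' @param n_subjects number of subjects (rows), at least 2.
#' @param n_snps number of SNPs (columns).
#' @param maf_low,maf_high bounds for the uniform MAF draw,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return An object of class `genotype_matrix`: a list with `dosages`
#'   (integer matrix, subjects x SNPs), `snp_ids`, `chrom`, `pos`, `maf`
#'   (the generating frequency), and allele labels `a1` (minor) / `a2`.
#' @examples
#' g <- simulate_genotypes(100, 50, seed = 1)
#' dim(g$dosages)
#' @export
simulate_genotypes <- function(n_subjects, n_snps,
                               maf_low = 0.05, maf_high = 0.5,
                               seed = 1) {
  if (n_subjects < 2) stopf("need at least 2 subjects")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stopf("invalid MAF bounds: need 0 < maf_low <= maf_high <= 0.5",
          class = "deepgwas_parameter_error")
  }
  with_seed(seed, {
    maf <- runif(n_snps, maf_low, maf_high)
    dos <- matrix(rbinom(n_subjects * n_snps, 2L, rep(maf, each = n_subjects)),
                  nrow = n_subjects, ncol = n_snps)
  })
  snp_ids <- sprintf("rs%06d", seq_len(n_snps))
  chrom <- rep_len(1:22, n_snps)
  # monotone positions within chromosome: 50kb spacing
  pos <- integer(n_snps)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 100000L + 50000L * (seq_along(idx) - 1L)
  }
  colnames(dos) <- snp_ids
  structure(
    list(dosages = dos, snp_ids = snp_ids, chrom = chrom, pos = pos,
         maf = maf, a1 = rep("A", n_snps), a2 = rep("B", n_snps)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs, MAF in [%.3f, %.3f]\n",
              nrow(x$dosages), ncol(x$dosages), min(x$maf), max(x$maf)))
  invisible(x)
}

# Restrict a genotype matrix to a subject subset (used by I/O round trips).
subset_genotypes <- function(g, rows) {
  g$dosages <- g$dosages[rows, , drop = FALSE]
  g
}
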