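# Shared simulation fixtures built in code at test time.

# Small multi-study design with one strong planted cis + disease SNP in
# its own haplotype block (so the planted signal has no LD proxies and
# "unique replicated hit" is well defined). The planted variant is a
# common SNP (MAF 0.2-0.5) with a 1.2 log2-units/allele cis effect and a
# 0.8 log-odds/allele disease effect.
e2e_config <- function(master_seed, n_snps = 60L, n_genes = 6L) {
  planted <- max(2L, n_snps %/% 2L)
  # blocks of (up to) four SNPs, with the planted SNP as a singleton block
  block4 <- function(lo, hi) {
    if (lo > hi) return(NULL)
    starts <- seq(lo, hi, 4L)
    data.frame(start = starts, end = c(starts[-1] - 1L, hi))
  }
  bb <- rbind(block4(1L, planted - 1L),
              data.frame(start = planted, end = planted),
              block4(planted + 1L, n_snps))
  sim_config(
    n_snps = n_snps, n_genes = n_genes, maf_range = c(0.2, 0.5),
    cis_effects = data.frame(snp = planted, probe = NA, beta = 1.2),
    disease_log_odds = stats::setNames(0.8, as.character(planted)),
    block_bounds = bb,
    master_seed = master_seed)
}

# Null design: independent SNPs (every SNP its own block), no planted
# effects.
null_config <- function(master_seed, n_snps = 60L, n_genes = 6L, ...) {
  sim_config(n_snps = n_snps, n_genes = n_genes,
             recomb_prob_between_blocks = 1,
             master_seed = master_seed, ...)
}

# A three-tag-block locus: three haplotype blocks of `block_size` SNPs
# each, equal within-block target frequencies (so within-block r^2 is
# near 1), low mutation.
tag_locus_config <- function(master_seed, block_size = 5L, n_blocks = 3L,
                             n_genes = 3L, ...) {
  n <- block_size * n_blocks
  sim_config(
    n_snps = n, n_genes = n_genes, maf_range = c(0.3, 0.3),
    mutation_prob = 0.01,
    block_bounds = data.frame(
      start = seq(1, n, block_size),
      end = seq(block_size, n, block_size)),
    master_seed = master_seed, ...)
}
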