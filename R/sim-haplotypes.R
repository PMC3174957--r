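#' Simulation configuration
#'
#' Defines the study design the generator emulates: a modest case-only
#' expression cohort genotyped genome-wide, several larger case-control
#' studies drawn from the same population, haplotype-block LD structure,
#' planted cis effects on expression and planted disease log-odds. Defaults
#' encode a sputum-eQTL-style design: 131 expression samples; three
#' discovery case-control studies and two replication studies (at one
#' quarter of the cohort sizes of the motivating design, so the combined
#' discovery set is 736 cases / 346 controls); covariates with age ~
#' N(65, 5.5), male fraction 0.66 and pack-years ~ N(47, 28) truncated at
#' zero.
#'
#' @param n_snps Number of SNPs on the simulated panel.
#' @param n_genes Number of genes (one expression probe per gene).
#' @param n_expression_samples Size of the expression cohort.
#' @param study_sizes List of `c(cases, controls)` pairs, one per discovery
#'   case-control study.
#' @param replication_sizes List of `c(cases, controls)` pairs for the
#'   replication studies.
#' @param maf_range Length-2 numeric in `(0, 0.5]`; per-SNP target minor
#'   allele frequencies are drawn uniformly from this interval.
#' @param recomb_prob_between_blocks Probability that a new haplotype block
#'   starts at each successive SNP (ignored when `block_bounds` is given).
#' @param block_bounds Optional data frame with columns `start`, `end`
#'   (1-based inclusive SNP indices) partitioning `1..n_snps`; overrides the
#'   random block layout, e.g. to engineer a tag-bin locus.
#' @param mutation_prob Per-site, per-haplotype allele flip probability;
#'   controls how far within-block r^2 falls below 1.
#' @param n_haplotypes Pool size; default twice the largest cohort, at
#'   least 2000.
#' @param cis_effects Data frame with columns `snp`, `probe`, `beta`
#'   (expression units per allele). `snp` is a SNP index or id; `probe` a
#'   gene index, probe id, or `NA` for the probe with the nearest TSS.
#' @param disease_log_odds Named numeric vector of per-allele log-odds;
#'   names are SNP indices or ids.
#' @param noise_sd Residual SD of expression (> 0).
#' @param covariate_effects List with elements `expression` and `disease`,
#'   each a named numeric vector over `age`, `sex`, `pack_years` (effects
#'   on centered covariates).
#' @param ancestry_divergence Allele-frequency divergence between two
#'   subpopulations (0 disables population structure).
#' @param snp_spacing_bp Mean spacing between adjacent SNPs, bp.
#' @param chrom Chromosome label for the simulated panel.
#' @param master_seed Integer master seed; every stage derives its own
#'   child stream from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 120L,
                       n_genes = 12L,
                       n_expression_samples = 131L,
                       study_sizes = list(c(434L, 44L), c(210L, 198L),
                                          c(92L, 104L)),
                       replication_sizes = list(c(246L, 469L),
                                                c(124L, 125L)),
                       maf_range = c(0.10, 0.50),
                       recomb_prob_between_blocks = 0.2,
                       block_bounds = NULL,
                       mutation_prob = 0.02,
                       n_haplotypes = NULL,
                       cis_effects = NULL,
                       disease_log_odds = NULL,
                       noise_sd = 1,
                       covariate_effects = list(
                         expression = c(age = 0.02, sex = 0.25),
                         disease = c(age = 0.03, pack_years = 0.01)),
                       ancestry_divergence = 0,
                       snp_spacing_bp = 2000,
                       chrom = "1",
                       master_seed = 1L) {
  if (n_snps < 1) stop("invalid config: n_snps must be >= 1", call. = FALSE)
  if (n_genes < 0) stop("invalid config: n_genes must be >= 0", call. = FALSE)
  if (n_expression_samples < 1) {
    stop("invalid config: n_expression_samples must be >= 1", call. = FALSE)
  }
  if (!(length(maf_range) == 2L && maf_range[1] > 0 &&
        maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2])) {
    stop("invalid config: maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (noise_sd <= 0) stop("invalid config: noise_sd must be > 0", call. = FALSE)
  sizes <- c(unlist(study_sizes), unlist(replication_sizes))
  if (length(sizes) && any(sizes < 1)) {
    stop("invalid config: all study sizes must be >= 1", call. = FALSE)
  }
  if (mutation_prob < 0 || mutation_prob >= 0.5) {
    stop("invalid config: mutation_prob must be in [0, 0.5)", call. = FALSE)
  }
  if (!is.null(block_bounds)) {
    block_bounds <- as.data.frame(block_bounds)
    stopifnot(all(c("start", "end") %in% names(block_bounds)))
    cover <- unlist(Map(seq, block_bounds$start, block_bounds$end))
    if (!identical(sort(as.integer(cover)), seq_len(n_snps))) {
      stop("invalid config: block_bounds must partition 1..n_snps",
           call. = FALSE)
    }
  }
  if (is.null(n_haplotypes)) {
    cohort_max <- max(c(n_expression_samples, vapply(
      c(study_sizes, replication_sizes), sum, numeric(1)), 0))
    n_haplotypes <- max(2L * as.integer(cohort_max), 2000L)
  }
  if (!is.null(cis_effects)) {
    cis_effects <- as.data.frame(cis_effects)
    stopifnot(all(c("snp", "probe", "beta") %in% names(cis_effects)))
  }
  structure(list(
    n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
    n_expression_samples = as.integer(n_expression_samples),
    study_sizes = study_sizes, replication_sizes = replication_sizes,
    maf_range = maf_range,
    recomb_prob_between_blocks = recomb_prob_between_blocks,
    block_bounds = block_bounds,
    mutation_prob = mutation_prob,
    n_haplotypes = as.integer(n_haplotypes),
    cis_effects = cis_effects,
    disease_log_odds = disease_log_odds,
    noise_sd = noise_sd,
    covariate_effects = covariate_effects,
    ancestry_divergence = ancestry_divergence,
    snp_spacing_bp = snp_spacing_bp,
    chrom = as.character(chrom),
    master_seed = as.integer(master_seed)
  ), class = "sim_config")
}

#' Simulate a haplotype pool with block LD structure
#'
#' Haplotypes are generated by a haplotype-ladder model: within each block
#' every haplotype draws one latent founder coordinate `u ~ Uniform(0, 1)`,
#' and carries the alternate allele at SNP `j` iff `u < p_j` (the SNP's
#' target frequency), after which each site is flipped independently with
#' `mutation_prob`. SNPs in the same block with similar frequencies are
#' therefore in strong LD (tag-SNP bins); SNPs with different frequencies
#' sit in moderate LD with them; SNPs in different blocks are independent.
#' Target frequencies are mutation-corrected so the post-mutation
#' expectation equals the drawn target.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"haplotype_pool"`: `haplotypes` (0/1 matrix,
#'   haplotypes x SNPs), `snp_meta`, `block_bounds` (data frame `start`,
#'   `end`, 1-based inclusive), `subpop` (integer vector, 1 or 2 per
#'   haplotype), `target_maf`.
#' @export
simulate_haplotype_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$master_seed, 1L))
  S <- cfg$n_snps
  H <- cfg$n_haplotypes
  # panel layout
  spacing <- pmax(1, round(stats::runif(S, 0.25, 1.75) * cfg$snp_spacing_bp))
  pos <- 1e6 + cumsum(spacing)
  snp_meta <- data.frame(
    id = sprintf("snp%04d", seq_len(S)), chrom = cfg$chrom, pos = pos,
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  # block partition
  if (is.null(cfg$block_bounds)) {
    starts <- c(TRUE, stats::runif(S - 1) < cfg$recomb_prob_between_blocks)
    block_id <- cumsum(starts)
  } else {
    block_id <- integer(S)
    for (b in seq_len(nrow(cfg$block_bounds))) {
      block_id[cfg$block_bounds$start[b]:cfg$block_bounds$end[b]] <- b
    }
  }
  bounds <- data.frame(
    start = match(unique(block_id), block_id),
    end = S + 1L - match(unique(block_id), rev(block_id)))
  # target frequencies, corrected so post-mutation expectation hits target
  p_target <- stats::runif(S, cfg$maf_range[1], cfg$maf_range[2])
  m <- cfg$mutation_prob
  p_gen <- pmin(pmax((p_target - m) / (1 - 2 * m), 0.005), 0.995)
  subpop <- rep(1L, H)
  div <- cfg$ancestry_divergence
  if (div > 0) subpop[seq_len(H %/% 2)] <- 2L
  shift <- c(div / 2, -div / 2)
  hap <- matrix(0L, nrow = H, ncol = S,
                dimnames = list(NULL, snp_meta$id))
  for (b in seq_len(nrow(bounds))) {
    js <- bounds$start[b]:bounds$end[b]
    u <- stats::runif(H)
    for (j in js) {
      pj <- pmin(pmax(p_gen[j] + shift[subpop], 0.005), 0.995)
      hap[, j] <- as.integer(u < pj)
    }
  }
  if (m > 0) {
    flips <- matrix(stats::runif(H * S) < m, nrow = H)
    hap[flips] <- 1L - hap[flips]
  }
  structure(list(haplotypes = hap, snp_meta = snp_meta,
                 block_bounds = bounds, subpop = subpop,
                 target_maf = p_target),
            class = "haplotype_pool")
}

#' Draw diploid genotypes from a haplotype pool
#'
#' Each sample is the sum of two haplotypes drawn with replacement; with
#' population structure, both haplotypes come from the sample's assigned
#' subpopulation (samples split evenly between the two).
#'
#' @param pool A `haplotype_pool`.
#' @param n_samples Number of diploid samples.
#' @param seed Integer seed for the draw.
#' @param sample_prefix Prefix for generated sample ids.
#' @return A [genotype_matrix()]; the per-sample subpopulation is attached
#'   as `attr(, "subpop")`.
#' @export
simulate_genotypes <- function(pool, n_samples, seed,
                               sample_prefix = "S") {
  stopifnot(inherits(pool, "haplotype_pool"), n_samples >= 1)
  if (nrow(pool$haplotypes) < 1L) stop("empty haplotype pool", call. = FALSE)
  set.seed(as.integer(seed))
  pops <- sort(unique(pool$subpop))
  if (length(pops) > 1L) {
    sample_pop <- rep(pops, length.out = n_samples)
    i1 <- integer(n_samples); i2 <- integer(n_samples)
    for (p in pops) {
      idx <- which(pool$subpop == p)
      sel <- which(sample_pop == p)
      i1[sel] <- sample(idx, length(sel), replace = TRUE)
      i2[sel] <- sample(idx, length(sel), replace = TRUE)
    }
  } else {
    sample_pop <- rep(1L, n_samples)
    H <- nrow(pool$haplotypes)
    i1 <- sample.int(H, n_samples, replace = TRUE)
    i2 <- sample.int(H, n_samples, replace = TRUE)
  }
  dos <- pool$haplotypes[i1, , drop = FALSE] +
    pool$haplotypes[i2, , drop = FALSE]
  ids <- sprintf("%s%04d", sample_prefix, seq_len(n_samples))
  G <- genotype_matrix(dos, pool$snp_meta, ids)
  attr(G, "subpop") <- sample_pop
  G
}
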