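test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(study_sizes = list(c(0, 10))), "study sizes")
  expect_error(sim_config(n_snps = 10,
                          block_bounds = data.frame(start = 1, end = 5)),
               "partition")
})

test_that("haplotype pool hits forced allele frequencies", {
  cfg <- sim_config(n_snps = 1, n_genes = 0, maf_range = c(0.5, 0.5),
                    mutation_prob = 0.02, n_haplotypes = 2000,
                    master_seed = 21)
  pool <- simulate_haplotype_pool(cfg)
  f <- mean(pool$haplotypes[, 1])
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(f - 0.5), 3 * se)
})

test_that("blocks partition the panel and LD respects block structure", {
  cfg <- sim_config(n_snps = 40, n_genes = 0, n_haplotypes = 2000,
                    recomb_prob_between_blocks = 0.3, master_seed = 22)
  pool <- simulate_haplotype_pool(cfg)
  covered <- unlist(Map(seq, pool$block_bounds$start, pool$block_bounds$end))
  expect_identical(sort(as.integer(covered)), seq_len(40L))
  # between-block independence
  cfg2 <- sim_config(n_snps = 2, n_genes = 0, n_haplotypes = 2000,
                     block_bounds = data.frame(start = 1:2, end = 1:2),
                     master_seed = 23)
  pool2 <- simulate_haplotype_pool(cfg2)
  r2 <- cor(pool2$haplotypes[, 1], pool2$haplotypes[, 2])^2
  expect_lt(r2, 0.05)
  # within-block r2 exceeds between-block r2 on average
  cfg3 <- tag_locus_config(24, block_size = 4, n_blocks = 3, n_genes = 0)
  pool3 <- simulate_haplotype_pool(cfg3)
  H <- pool3$haplotypes
  blocks <- rep(1:3, each = 4)
  R <- cor(H)^2
  same <- outer(blocks, blocks, "==") & upper.tri(R)
  diff <- outer(blocks, blocks, "!=") & upper.tri(R)
  expect_gt(mean(R[same]), mean(R[diff]))
})

test_that("identical master seeds give identical pools and bundles", {
  cfg <- function() e2e_config(77, n_snps = 20, n_genes = 2)
  p1 <- simulate_haplotype_pool(cfg())
  p2 <- simulate_haplotype_pool(cfg())
  expect_identical(p1, p2)
  b1 <- generate_study_bundle(cfg())
  b2 <- generate_study_bundle(cfg())
  expect_identical(b1$expression$values, b2$expression$values)
  expect_identical(b1$studies[[1]]$phenotype, b2$studies[[1]]$phenotype)
})

test_that("genotype draws are haplotype sums obeying Hardy-Weinberg", {
  meta1 <- data.frame(id = "s1", chrom = "1", pos = 100, ref = "A",
                      alt = "G")
  zero_pool <- structure(list(
    haplotypes = matrix(0L, 1, 1), snp_meta = meta1,
    block_bounds = data.frame(start = 1, end = 1), subpop = 1L),
    class = "haplotype_pool")
  G0 <- simulate_genotypes(zero_pool, 10, seed = 1)
  expect_true(all(G0$dosages == 0))
  one_pool <- zero_pool
  one_pool$haplotypes <- matrix(1L, 1, 1)
  G2 <- simulate_genotypes(one_pool, 10, seed = 1)
  expect_true(all(G2$dosages == 2))
  # Hardy-Weinberg proportions within 3 binomial SEs at n = 2000
  cfg <- sim_config(n_snps = 1, n_genes = 0, maf_range = c(0.3, 0.3),
                    mutation_prob = 0, n_haplotypes = 4000,
                    master_seed = 31)
  pool <- simulate_haplotype_pool(cfg)
  p <- mean(pool$haplotypes[, 1])
  G <- simulate_genotypes(pool, 2000, seed = 32)
  counts <- table(factor(G$dosages[, 1], levels = 0:2)) / 2000
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  for (i in 1:3) {
    se <- sqrt(hw[i] * (1 - hw[i]) / 2000)
    expect_lt(abs(counts[i] - hw[i]), 3 * se)
  }
})

test_that("expression generator obeys its variance and mean structure", {
  cfg <- null_config(41, n_snps = 10, n_genes = 4)
  pool <- simulate_haplotype_pool(cfg)
  G <- simulate_genotypes(pool, 800, seed = 42)
  cov <- simulate_covariates(800, seed = 43, sample_ids = G$sample_ids)
  # no planted effects: per-probe variance = noise^2 + covariate variance
  sim <- simulate_expression(G, simulate_annotation(pool$snp_meta, 4),
                             covariates = cov,
                             covariate_effects = c(age = 0.02, sex = 0.25),
                             noise_sd = 1, seed = 44)
  cov_var <- var(0.02 * cov$age + 0.25 * cov$sex)
  target <- 1 + cov_var
  v <- apply(sim$expression$values, 2, var)
  se_v <- target * sqrt(2 / (800 - 1))  # SE of a sample variance
  expect_true(all(abs(v - target) < 3.5 * se_v))
  # a huge planted effect with tiny noise forces the dosage-group means
  sim2 <- simulate_expression(
    G, simulate_annotation(pool$snp_meta, 4),
    cis_effects = data.frame(snp = G$snp_meta$id[3], probe = 2, beta = 5),
    noise_sd = 0.01, seed = 45)
  E <- sim2$expression$values[, 2]
  g <- G$dosages[, 3]
  mm <- tapply(E, g, mean)
  expect_equal(as.numeric(diff(mm)), c(5, 5), tolerance = 0.05)
  expect_identical(sim2$truth$snp_id, G$snp_meta$id[3])
  # determinism
  sim3 <- simulate_expression(G, simulate_annotation(pool$snp_meta, 4),
                              covariates = cov, noise_sd = 1, seed = 44,
                              covariate_effects = c(age = 0.02, sex = 0.25))
  expect_identical(sim$expression$values, sim3$expression$values)
})

test_that("a planted SNP outside the cis window is rejected", {
  cfg <- null_config(46, n_snps = 50, n_genes = 1)
  pool <- simulate_haplotype_pool(cfg)
  G <- simulate_genotypes(pool, 20, seed = 47)
  ann <- simulate_annotation(pool$snp_meta, 1)  # TSS near the panel centre
  far <- which.max(abs(pool$snp_meta$pos - ann$tss))
  expect_error(
    simulate_expression(G, ann,
                        cis_effects = data.frame(snp = far, probe = 1,
                                                 beta = 1),
                        cis_window_bp = 1000),
    "invalid config")
})

test_that("case-control liabilities follow the logistic model", {
  cfg <- null_config(51, n_snps = 5, n_genes = 0)
  pool <- simulate_haplotype_pool(cfg)
  G <- simulate_genotypes(pool, 2000, seed = 52)
  y <- simulate_case_control(G, baseline_log_odds = 0, seed = 53)
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / 2000))
  y0 <- simulate_case_control(G, baseline_log_odds = -20, seed = 54)
  expect_true(all(y0 == 0))
  # parameter recovery: gamma = 1 within 2 SE at n = 4000
  G4 <- simulate_genotypes(pool, 4000, seed = 55)
  y1 <- simulate_case_control(G4, c("3" = 1), baseline_log_odds = -1,
                              seed = 56)
  fit <- logistic_assoc(unname(y1), G4$dosages[, 3])
  expect_lt(abs(fit$effect - 1), 2 * fit$se)
})

test_that("study bundles honour the configured design", {
  cfg <- e2e_config(61, n_snps = 20, n_genes = 2)
  b <- generate_study_bundle(cfg)
  roles <- vapply(b$studies, `[[`, character(1), "role")
  expect_identical(unname(table(roles)["discovery"]),
                   length(cfg$study_sizes))
  for (i in seq_along(cfg$study_sizes)) {
    expect_length(b$studies[[i]]$phenotype, sum(cfg$study_sizes[[i]]))
  }
  # planted ids exist in the emitted dataset
  expect_true(all(b$truth$snp_id %in% b$pool$snp_meta$id))
  cis <- b$truth[b$truth$kind == "cis", ]
  expect_true(all(cis$probe_id %in% b$annotation$probe_id))
  # realized case fractions sit near the design fractions
  for (st in b$studies) {
    frac <- st$target_size[1] / sum(st$target_size)
    expect_lt(abs(mean(st$phenotype) - frac), 0.15)
  }
})
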