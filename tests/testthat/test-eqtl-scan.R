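test_that("filter_probes keeps annotated autosomal probes in order", {
  ann <- data.frame(
    probe_id = paste0("p", 1:5),
    gene_symbol = c("A", "", "B", NA, "C"),
    chrom = c("1", "2", "X", "3", "chrY"),
    tss = rep(100, 5), strand = "+", stringsAsFactors = FALSE)
  kept <- filter_probes(ann)
  expect_identical(kept$probe_id, "p1")  # p3 on X, p5 on Y, p2/p4 unnamed
  ann$chrom <- "5"
  kept <- filter_probes(ann)
  expect_identical(kept$probe_id, c("p1", "p3", "p5"))
})

test_that("filter_snps applies a strict MAF threshold on the cohort", {
  # 500 samples, 1000 alleles: 49 alt alleles -> MAF 0.049 (excluded),
  # 50 -> 0.05 (kept at the boundary), 0 -> monomorphic (excluded)
  d049 <- c(rep(1, 49), rep(0, 451))
  d050 <- c(rep(1, 50), rep(0, 450))
  dmono <- rep(0, 500)
  dcommon <- rep(c(0, 1, 2), length.out = 500)
  meta <- data.frame(id = c("a", "b", "c", "d"), chrom = "1",
                     pos = 1:4 * 1000, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  G <- genotype_matrix(cbind(d049, d050, dmono, dcommon), meta)
  expect_identical(filter_snps(G, 0.05), c("b", "d"))
})

test_that("cis pair enumeration respects window, strand and ordering", {
  snps <- data.frame(id = paste0("s", 1:5), chrom = "1",
                     pos = c(100000, 149999, 150000, 150001, 200001),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = "p1", gene_symbol = "G1", chrom = "1",
                    tss = 100000, strand = "+", stringsAsFactors = FALSE)
  pairs <- enumerate_cis_pairs(snps, ann, 50000)
  expect_identical(pairs$snp_id, c("s1", "s2", "s3"))  # 150001 excluded
  expect_identical(pairs$distance, c(0, 49999, 50000))
  # minus strand flips the sign of the distance
  ann$strand <- "-"
  pairs <- enumerate_cis_pairs(snps, ann, 50000)
  expect_identical(pairs$distance, c(0, -49999, -50000))
  # exhaustive-enumeration oracle on a 3-gene / 5-SNP map
  set.seed(71)
  snps2 <- data.frame(id = paste0("s", 1:5),
                      chrom = c("1", "1", "2", "2", "2"),
                      pos = c(5000, 90000, 10000, 20000, 70000),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  ann2 <- data.frame(probe_id = paste0("p", 1:3),
                     gene_symbol = paste0("G", 1:3),
                     chrom = c("1", "2", "2"),
                     tss = c(10000, 15000, 60000),
                     strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  pairs2 <- enumerate_cis_pairs(snps2, ann2, 20000)
  want <- list()
  for (i in 1:3) for (j in 1:5) {
    if (snps2$chrom[j] == ann2$chrom[i] &&
        abs(snps2$pos[j] - ann2$tss[i]) <= 20000) {
      want[[length(want) + 1]] <- paste(snps2$id[j], ann2$probe_id[i])
    }
  }
  expect_setequal(paste(pairs2$snp_id, pairs2$probe_id), unlist(want))
})

test_that("window enlargement yields a superset of cis pairs", {
  cfg <- null_config(72, n_snps = 80, n_genes = 8)
  pool <- simulate_haplotype_pool(cfg)
  ann <- simulate_annotation(pool$snp_meta, 8)
  p50 <- enumerate_cis_pairs(pool$snp_meta, ann, 50000)
  p200 <- enumerate_cis_pairs(pool$snp_meta, ann, 200000)
  expect_true(all(paste(p50$snp_id, p50$probe_id) %in%
                    paste(p200$snp_id, p200$probe_id)))
  expect_gte(nrow(p200), nrow(p50))
})

scan_fixture <- function(seed, beta = 0, noise_sd = 1) {
  cfg <- null_config(seed, n_snps = 30, n_genes = 3)
  if (beta != 0) {
    cfg <- sim_config(n_snps = 30, n_genes = 3,
                      recomb_prob_between_blocks = 1,
                      cis_effects = data.frame(snp = 5, probe = 1,
                                               beta = beta),
                      noise_sd = noise_sd, master_seed = seed)
  }
  b <- generate_study_bundle(cfg)
  pairs <- enumerate_cis_pairs(b$genotypes$snp_meta, b$annotation, 50000)
  cov <- cbind(age = b$covariates$age, sex = b$covariates$sex)
  list(bundle = b, pairs = pairs, cov = cov)
}

test_that("the scan recovers a planted effect with joint FDR control", {
  fx <- scan_fixture(81, beta = 2, noise_sd = 0.5)
  rec <- run_cis_scan(fx$bundle$genotypes, fx$bundle$expression, fx$cov,
                      fx$pairs)
  planted <- fx$bundle$truth[fx$bundle$truth$kind == "cis", ]
  hit <- rec$snp_id == planted$snp_id & rec$probe_id == planted$probe_id
  expect_true(any(hit))
  expect_equal(which.min(rec$p), which(hit))
  expect_lt(rec$fdr_p[hit], 0.05)
  expect_true(all(rec$fdr_p >= rec$p, na.rm = TRUE))
})

test_that("degenerate SNPs are flagged and excluded from the FDR ranking", {
  fx <- scan_fixture(82)
  G <- fx$bundle$genotypes
  G$dosages[, 2] <- 0  # force a zero-variance SNP
  rec <- run_cis_scan(G, fx$bundle$expression, fx$cov, fx$pairs)
  degen <- rec$snp_id == G$snp_meta$id[2]
  if (any(degen)) {
    expect_true(all(rec$flag[degen] == "degenerate"))
    expect_true(all(is.na(rec$fdr_p[degen])))
  }
  expect_false(anyNA(rec$fdr_p[!is.na(rec$p)]))
  empty <- run_cis_scan(G, fx$bundle$expression, fx$cov, fx$pairs[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("scan output is reproducible and summaries recount records", {
  fx <- scan_fixture(83)
  r1 <- run_cis_scan(fx$bundle$genotypes, fx$bundle$expression, fx$cov,
                     fx$pairs)
  r2 <- run_cis_scan(fx$bundle$genotypes, fx$bundle$expression, fx$cov,
                     fx$pairs)
  expect_identical(r1, r2)
  s <- summarize_eqtls(r1, 0.05)
  sig <- r1[!is.na(r1$fdr_p) & r1$fdr_p < 0.05, ]
  expect_identical(s$n_significant_pairs, nrow(sig))
  expect_identical(s$n_unique_snps, length(unique(sig$snp_id)))
  expect_identical(s$n_unique_probes, length(unique(sig$probe_id)))
  expect_identical(s$n_unique_genes, length(unique(sig$gene_symbol)))
  # toy counting example: two significant pairs, one SNP, two probes,
  # one gene
  toy <- data.frame(snp_id = c("s", "s"), probe_id = c("p1", "p2"),
                    gene_symbol = "G", p = c(1e-5, 1e-5),
                    fdr_p = c(0.01, 0.01), stringsAsFactors = FALSE)
  s2 <- summarize_eqtls(toy, 0.05)
  expect_identical(
    unlist(s2[c("n_significant_pairs", "n_unique_snps", "n_unique_probes",
                "n_unique_genes")], use.names = FALSE),
    c(2L, 1L, 2L, 1L))
  none <- summarize_eqtls(toy, 1e-9)
  expect_identical(none$n_significant_pairs, 0L)
  expect_true(is.na(none$max_raw_p_among_significant))
})

test_that("lowering the FDR threshold never grows any summary count", {
  fx <- scan_fixture(84, beta = 1, noise_sd = 1)
  rec <- run_cis_scan(fx$bundle$genotypes, fx$bundle$expression, fx$cov,
                      fx$pairs)
  alphas <- c(0.5, 0.2, 0.05, 0.01)
  sums <- lapply(alphas, function(a) summarize_eqtls(rec, a))
  for (i in 2:length(alphas)) {
    for (f in c("n_significant_pairs", "n_unique_snps", "n_unique_probes",
                "n_unique_genes")) {
      expect_lte(sums[[i]][[f]], sums[[i - 1]][[f]])
    }
  }
})

test_that("permuting sample labels destroys planted-signal detection", {
  fx <- scan_fixture(85, beta = 1.2, noise_sd = 1)
  b <- fx$bundle
  planted <- b$truth[b$truth$kind == "cis", ]
  not_first <- 0
  set.seed(86)
  for (perm in 1:50) {
    idx <- sample(nrow(b$expression$values))
    Eperm <- expression_matrix(b$expression$values[idx, , drop = FALSE],
                               b$annotation, b$expression$sample_ids)
    rec <- run_cis_scan(b$genotypes, Eperm, fx$cov[idx, ], fx$pairs)
    top <- rec[which.min(rec$p), ]
    if (!(top$snp_id == planted$snp_id &&
          top$probe_id == planted$probe_id)) {
      not_first <- not_first + 1
    }
  }
  expect_gte(not_first / 50, 0.95)
})
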