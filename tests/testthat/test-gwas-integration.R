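gwas_fixture <- function(seed, gamma = 0, n = 1200) {
  cfg <- sim_config(n_snps = 20, n_genes = 0, maf_range = c(0.2, 0.5),
                    recomb_prob_between_blocks = 1,
                    disease_log_odds = if (gamma != 0) c("7" = gamma),
                    study_sizes = list(c(n / 2, n / 2)),
                    replication_sizes = list(), master_seed = seed)
  b <- generate_study_bundle(cfg)
  st <- b$studies[[1]]
  list(G = st$genotypes, y = unname(st$phenotype),
       cov = cbind(age = st$covariates$age,
                   pack_years = st$covariates$pack_years))
}

test_that("run_gwas recovers a planted disease effect and flags failures", {
  fx <- gwas_fixture(91, gamma = 0.8, n = 4000)
  rec <- run_gwas(fx$G, fx$y, fx$cov, study_label = "s1")
  hit <- rec[rec$snp_id == "snp0007", ]
  expect_lt(abs(hit$effect - 0.8), 2 * hit$se)
  expect_equal(hit$or, exp(hit$effect))
  expect_identical(hit$direction, 1)
  # monomorphic SNP: flagged, not dropped
  G <- fx$G
  G$dosages[, 3] <- 2
  rec2 <- run_gwas(G, fx$y, fx$cov)
  expect_identical(rec2$flag[rec2$snp_id == G$snp_meta$id[3]], "degenerate")
  expect_identical(nrow(rec2), ncol(G$dosages))
})

test_that("effects are reported for the minor allele", {
  set.seed(92)
  meta <- data.frame(id = c("a", "b"), chrom = "1", pos = c(1, 2) * 1000,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  g_major <- rbinom(400, 2, 0.8)  # ALT is the major allele here
  g_minor <- rbinom(400, 2, 0.2)
  G <- genotype_matrix(cbind(g_major, g_minor), meta)
  y <- rbinom(400, 1, plogis(0.5 * g_major - 1))
  rec <- run_gwas(G, y)
  expect_identical(rec$effect_allele[rec$snp_id == "a"], "A")  # flipped
  expect_identical(rec$effect_allele[rec$snp_id == "b"], "G")
  # flipping the counted allele negates the log-odds
  direct <- logistic_assoc(y, 2 - g_major)
  expect_equal(rec$effect[rec$snp_id == "a"], direct$effect,
               tolerance = 1e-8)
})

test_that("run_meta matches the IVW oracle and is harmonization-invariant", {
  fx1 <- gwas_fixture(93, gamma = 0.5, n = 1000)
  r1 <- run_gwas(fx1$G, fx1$y, fx1$cov, study_label = "s1")
  # single study: meta equals the study records
  m1 <- run_meta(list(r1))
  expect_equal(m1$effect, r1$effect, tolerance = 1e-12)
  expect_equal(m1$p, r1$p, tolerance = 1e-12)
  # duplicated study: z inflated by sqrt(2)
  m2 <- run_meta(list(r1, r1))
  expect_equal(m2$statistic, r1$statistic * sqrt(2), tolerance = 1e-10)
  # three simulated studies against the longhand IVW oracle
  recs <- lapply(94:96, function(s) {
    fx <- gwas_fixture(s, gamma = 0.5, n = 800)
    run_gwas(fx$G, fx$y, fx$cov, study_label = paste0("s", s))
  })
  m3 <- run_meta(recs)
  for (snp in m3$snp_id) {
    eff <- vapply(recs, function(r) r$effect[r$snp_id == snp], numeric(1))
    ses <- vapply(recs, function(r) r$se[r$snp_id == snp], numeric(1))
    al <- vapply(recs, function(r) r$effect_allele[r$snp_id == snp],
                 character(1))
    eff <- ifelse(al == al[1], eff, -eff)
    ok <- is.finite(eff) & is.finite(ses)
    want <- oracle_ivw(eff[ok], ses[ok])
    expect_equal(m3$effect[m3$snp_id == snp], want$effect,
                 tolerance = 1e-10)
  }
  # flipping one study's allele labels leaves meta z-scores invariant
  flipped <- recs
  flipped[[2]]$effect <- -flipped[[2]]$effect
  flipped[[2]]$effect_allele <- ifelse(flipped[[2]]$effect_allele == "G",
                                       "A", "G")
  m4 <- run_meta(flipped)
  expect_equal(abs(m4$statistic), abs(m3$statistic), tolerance = 1e-10)
})

test_that("Bonferroni prioritization applies the reduced-set threshold", {
  rec <- data.frame(snp_id = c("x", "y", "z"), study_label = "combined",
                    effect_allele = "G", effect = c(-0.29, 0.25, 0.01),
                    se = 0.06, statistic = 1, or = 1,
                    p = c(6.8e-06, 2.8e-06, 0.5), direction = c(-1, 1, 1),
                    n_used = 4320L, flag = NA_character_,
                    stringsAsFactors = FALSE)
  pr <- prioritize_bonferroni(paste0("s", 1:3309), rec[0, ], 0.05)
  expect_equal(signif(pr$threshold, 2), 1.5e-5)
  pr2 <- prioritize_bonferroni(c("x", "y", "z", paste0("s", 1:3306)), rec,
                               0.05)
  expect_setequal(pr2$significant$snp_id, c("x", "y"))
  rec$p <- 0.5
  pr3 <- prioritize_bonferroni(c("x", "y", "z"), rec, 0.05)
  expect_identical(nrow(pr3$significant), 0L)
  expect_error(prioritize_bonferroni(character(), rec), "empty")
})

test_that("nominal candidate union tracks provenance and exclusions", {
  mk <- function(ids, ps) {
    data.frame(snp_id = ids, p = ps, direction = 1,
               stringsAsFactors = FALSE)
  }
  # 64 combined hits and 56 meta hits overlapping in 44 -> 76 unique
  comb_ids <- paste0("c", 1:64)
  meta_ids <- c(paste0("c", 1:44), paste0("m", 1:12))
  all_ids <- unique(c(comb_ids, meta_ids, paste0("n", 1:10)))
  comb <- mk(all_ids, ifelse(all_ids %in% comb_ids, 0.001, 0.5))
  met <- mk(all_ids, ifelse(all_ids %in% meta_ids, 0.001, 0.5))
  cand <- select_nominal_candidates(comb, met, 0.01)
  expect_identical(nrow(cand), 76L)
  expect_identical(sum(cand$provenance == "both"), 44L)
  expect_identical(sum(cand$provenance == "combined"), 20L)
  expect_identical(sum(cand$provenance == "meta"), 12L)
  # disjoint sets of sizes 2 and 3 -> 5
  cand2 <- select_nominal_candidates(mk(c("a", "b"), c(0.001, 0.002)),
                                     mk(c("d", "e", "f"), rep(0.001, 3)),
                                     0.01)
  expect_identical(nrow(cand2), 5L)
  # empty inputs and exclusion of established SNPs
  expect_identical(nrow(select_nominal_candidates(mk("a", 0.5),
                                                  mk("b", 0.5), 0.01)), 0L)
  cand3 <- select_nominal_candidates(comb, met, 0.01,
                                     exclude = c("c1", "c2"))
  expect_identical(nrow(cand3), 74L)
})

test_that("the sequential replication screen enforces both passes", {
  cand <- data.frame(snp_id = c("rsA", "rsB", "rsC", "rsD"),
                     direction_combined = c(1, 1, -1, 1),
                     stringsAsFactors = FALSE)
  s1 <- data.frame(snp_id = c("rsA", "rsB", "rsC"),
                   p = c(0.024, 0.042, 0.5), direction = c(1, 1, -1),
                   stringsAsFactors = FALSE)
  s2 <- data.frame(snp_id = c("rsA", "rsB", "rsC"),
                   p = c(0.098, 0.53, 0.01),
                   direction = c(sign(log(1.20)), sign(log(0.94)), -1),
                   stringsAsFactors = FALSE)
  out <- replication_screen(cand, s1, s2, 0.1)
  expect_identical(out$replicated, c(TRUE, FALSE, FALSE, FALSE))
  # rsB fails pass 2 (p and direction), rsC fails pass 1, rsD untested
  expect_false(out$tested[out$snp_id == "rsD"])
  expect_true(out$pass_screen1[out$snp_id == "rsB"])
  # without the direction requirement rsB still fails on p alone
  out2 <- replication_screen(cand, s1, s2, 0.1, require_direction = FALSE)
  expect_identical(out2$replicated, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("the reduced SNP set relaxes the threshold yet controls error", {
  # threshold over an eQTL subset (dozens of SNPs) is strictly more
  # permissive than the genome-wide threshold over a 550k-SNP chip panel
  m_all <- 550000L
  m_eqtl <- 50L
  thr_eqtl <- bonferroni_threshold(0.05, m_eqtl)
  thr_all <- bonferroni_threshold(0.05, m_all)
  expect_gt(thr_eqtl, thr_all)
  # a moderate planted effect (OR ~ 1.4) passes the reduced threshold but
  # not the genome-wide one in a majority of replicates
  both <- 0; reduced_only <- 0
  for (s in 1:30) {
    cfg <- sim_config(n_snps = 5, n_genes = 0, maf_range = c(0.3, 0.5),
                      recomb_prob_between_blocks = 1,
                      disease_log_odds = c("3" = 0.33),
                      study_sizes = list(c(750, 750)),
                      replication_sizes = list(), master_seed = 700 + s)
    st <- generate_study_bundle(cfg)$studies[[1]]
    fit <- logistic_assoc(unname(st$phenotype), st$genotypes$dosages[, 3])
    if (!is.na(fit$p) && fit$p < thr_eqtl) {
      if (fit$p < thr_all) both <- both + 1 else reduced_only <- reduced_only + 1
    }
  }
  expect_gt(reduced_only, 15)   # reduced-burden detection in a majority
  expect_gt(reduced_only, both) # while mostly missed genome-wide
})
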