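#' Run the full two-stage integrative pipeline
#'
#' Chains every stage on a study bundle (simulated via
#' [generate_study_bundle()] or read from disk via [read_study_inputs()]):
#'
#' 1. probe filtering (annotated, autosomal) and SNP filtering (MAF on the
#'    expression cohort);
#' 2. genotype ancestry PCs on the post-filter expression-cohort matrix;
#' 3. cis-pair enumeration and the covariate-adjusted eQTL scan with joint
#'    BH adjustment; FDR summary;
#' 4. disease association of the significant eQTL SNPs: pooled
#'    mega-analysis over the discovery studies (logistic regression with
#'    study indicators, age, pack-years and pooled-cohort PCs) and
#'    fixed-effects meta-analysis of the per-study fits;
#' 5. Bonferroni prioritization over the reduced eQTL SNP set and the
#'    nominal candidate union;
#' 6. the sequential two-cohort replication screen on the replication
#'    studies (largest first).
#'
#' When `out_dir` is given, every stage table is written as TSV and a JSON
#' run manifest is placed in the directory.
#'
#' @param bundle A `"study_bundle"` or the list returned by
#'   [read_study_inputs()].
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `"pipeline_result"`: `kept_probes`,
#'   `kept_snps`, `eqtl_records`, `eqtl_summary`, `eqtl_snp_ids`,
#'   `combined_records`, `study_records`, `meta_records`,
#'   `prioritization`, `candidates`, `replication_records`, `replication`.
#' @export
run_pipeline <- function(bundle, cfg = pipeline_config(), out_dir = NULL) {
  ann <- filter_probes(bundle$annotation)
  Ge <- bundle$genotypes
  kept_snps <- filter_snps(Ge, cfg$maf_min)
  Gf <- subset_snps(Ge, kept_snps)

  # ancestry PCs on the MAF-filtered expression-cohort genotypes
  n_pcs <- min(cfg$n_pcs, nrow(Gf$dosages) - 2L, ncol(Gf$dosages))
  pcs <- if (n_pcs > 0) genotype_pcs(Gf, n_pcs) else NULL
  cov_idx <- match(Ge$sample_ids, bundle$covariates$sample_id)
  expr_cov <- cbind(age = bundle$covariates$age[cov_idx],
                    sex = bundle$covariates$sex[cov_idx], pcs)

  pairs <- enumerate_cis_pairs(Gf$snp_meta, ann, cfg$cis_window_bp)
  Ef <- bundle$expression
  keep_pr <- Ef$annotation$probe_id %in% ann$probe_id
  Ef <- expression_matrix(Ef$values[, keep_pr, drop = FALSE],
                          Ef$annotation[keep_pr, , drop = FALSE],
                          Ef$sample_ids)
  eqtl_records <- run_cis_scan(Gf, Ef, expr_cov, pairs, cfg)
  eqtl_summary <- summarize_eqtls(eqtl_records, cfg$fdr_alpha)
  sig <- !is.na(eqtl_records$fdr_p) & eqtl_records$fdr_p < cfg$fdr_alpha
  eqtl_snp_ids <- unique(eqtl_records$snp_id[sig])

  roles <- vapply(bundle$studies, `[[`, character(1), "role")
  discovery <- bundle$studies[roles == "discovery"]
  replication <- bundle$studies[roles == "replication"]

  combined_records <- NULL
  study_records <- list()
  meta_records <- NULL
  prioritization <- NULL
  candidates <- NULL
  replication_records <- list()
  replication_out <- NULL

  if (length(eqtl_snp_ids) && length(discovery)) {
    gwas_cov <- function(st, pcs_mat) {
      cbind(age = st$covariates$age, pack_years = st$covariates$pack_years,
            pcs_mat)
    }
    study_pcs <- function(G) {
      k <- min(cfg$n_pcs, nrow(G$dosages) - 2L, ncol(G$dosages))
      if (k > 0) genotype_pcs(G, k) else NULL
    }
    # pooled mega-analysis with study-indicator covariates
    pool_dos <- do.call(rbind, lapply(discovery,
                                      function(s) s$genotypes$dosages))
    pool_meta <- discovery[[1]]$genotypes$snp_meta
    pool_ids <- unlist(lapply(discovery, function(s) s$genotypes$sample_ids))
    Gpool <- genotype_matrix(pool_dos, pool_meta, pool_ids)
    pool_pheno <- unlist(lapply(discovery, `[[`, "phenotype"))
    pool_cov <- do.call(rbind, lapply(discovery, function(s) {
      data.frame(age = s$covariates$age,
                 pack_years = s$covariates$pack_years)
    }))
    if (length(discovery) > 1L) {
      study_of <- rep(seq_along(discovery),
                      vapply(discovery, function(s) length(s$phenotype),
                             integer(1)))
      for (k in 2:length(discovery)) {
        pool_cov[[paste0("study", k)]] <- as.numeric(study_of == k)
      }
    }
    pool_cov <- cbind(pool_cov, study_pcs(Gpool))
    combined_records <- run_gwas(Gpool, pool_pheno, pool_cov,
                                 snp_ids = eqtl_snp_ids,
                                 study_label = "combined")
    # per-study fits for the meta-analysis
    study_records <- lapply(discovery, function(s) {
      run_gwas(s$genotypes, s$phenotype,
               gwas_cov(s, study_pcs(s$genotypes)),
               snp_ids = eqtl_snp_ids, study_label = s$label)
    })
    meta_records <- run_meta(study_records, method = cfg$meta_method)
    prioritization <- prioritize_bonferroni(eqtl_snp_ids, combined_records,
                                            cfg$fwer_alpha)
    exclude <- if (cfg$exclude_bonferroni_from_replication) {
      prioritization$significant$snp_id
    } else {
      character()
    }
    candidates <- select_nominal_candidates(combined_records, meta_records,
                                            cfg$nominal_p, exclude)
    if (nrow(candidates) && length(replication) >= 2L) {
      sizes <- vapply(replication, function(s) length(s$phenotype),
                      numeric(1))
      replication <- replication[order(-sizes)]
      replication_records <- lapply(replication[1:2], function(s) {
        run_gwas(s$genotypes, s$phenotype,
                 gwas_cov(s, study_pcs(s$genotypes)),
                 snp_ids = intersect(candidates$snp_id,
                                     s$genotypes$snp_meta$id),
                 study_label = s$label)
      })
      replication_out <- replication_screen(
        candidates, replication_records[[1]], replication_records[[2]],
        cfg$replication_p, cfg$require_direction)
    }
  }

  res <- structure(list(
    kept_probes = ann, kept_snps = kept_snps,
    eqtl_records = eqtl_records, eqtl_summary = eqtl_summary,
    eqtl_snp_ids = eqtl_snp_ids,
    combined_records = combined_records, study_records = study_records,
    meta_records = meta_records, prioritization = prioritization,
    candidates = candidates, replication_records = replication_records,
    replication = replication_out, config = cfg
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(res, bundle, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$eqtl_summary
  cat(sprintf(paste0(
    "pipeline_result\n",
    "  cis tests: %d; FDR<%.2g: %d pairs, %d SNPs, %d probes, %d genes\n"),
    s$n_tests, x$config$fdr_alpha, s$n_significant_pairs, s$n_unique_snps,
    s$n_unique_probes, s$n_unique_genes))
  if (!is.null(x$prioritization)) {
    cat(sprintf("  Bonferroni threshold %.3g over %d SNPs: %d significant\n",
                x$prioritization$threshold, x$prioritization$n_tests,
                nrow(x$prioritization$significant)))
  }
  if (!is.null(x$candidates)) {
    cat(sprintf("  nominal candidates (p<%.2g): %d\n",
                x$config$nominal_p, nrow(x$candidates)))
  }
  if (!is.null(x$replication)) {
    cat(sprintf("  replicated: %d of %d tested candidates\n",
                sum(x$replication$replicated, na.rm = TRUE),
                sum(x$replication$tested)))
  }
  invisible(x)
}

write_pipeline_result <- function(res, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) format(df, digits = 17, trim = TRUE, scientific = NA)
  write_tsv(fmt(res$eqtl_records), file.path(out_dir, "eqtl_records.tsv"))
  if (!is.null(res$combined_records)) {
    write_tsv(fmt(res$combined_records),
              file.path(out_dir, "assoc_combined.tsv"))
    for (nm in names(res$study_records)) {
      write_tsv(fmt(res$study_records[[nm]]),
                file.path(out_dir, paste0("assoc_", nm, ".tsv")))
    }
    write_tsv(fmt(res$meta_records), file.path(out_dir, "assoc_meta.tsv"))
  }
  if (!is.null(res$candidates)) {
    write_tsv(fmt(res$candidates), file.path(out_dir, "candidates.tsv"))
  }
  if (!is.null(res$replication)) {
    for (nm in names(res$replication_records)) {
      write_tsv(fmt(res$replication_records[[nm]]),
                file.path(out_dir, paste0("assoc_", nm, ".tsv")))
    }
    write_tsv(fmt(res$replication), file.path(out_dir, "replication.tsv"))
  }
  seed <- tryCatch(bundle$config$master_seed, error = function(e) NA)
  write_manifest(out_dir, res$config, seed = seed)
  invisible(out_dir)
}
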