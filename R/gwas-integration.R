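#' Per-SNP case-control association
#'
#' Logistic regression of disease status on additive dosage for each SNP
#' in a subset, adjusted for covariates (in the pipeline: age, pack-years
#' and ancestry PCs). Effects are reported for the minor allele: columns
#' whose ALT frequency exceeds 0.5 in the analyzed cohort are flipped, and
#' the counted allele is recorded as `effect_allele`. Degenerate fits
#' (monomorphic SNPs, separation) are flagged, never dropped silently.
#'
#' @param G A [genotype_matrix()].
#' @param phenotype Binary 0/1 vector aligned to the samples.
#' @param covariates Covariate matrix / data frame aligned to the samples
#'   (or `NULL`).
#' @param snp_ids SNPs to test (default: all SNPs in `G`).
#' @param study_label Label recorded on every record.
#' @return Data frame of association records: `snp_id`, `study_label`,
#'   `effect_allele`, `effect` (log-odds per minor allele), `se`,
#'   `statistic` (z), `p`, `or` (`exp(effect)`), `direction` (+1/-1),
#'   `n_used`, `flag`.
#' @export
run_gwas <- function(G, phenotype, covariates = NULL, snp_ids = NULL,
                     study_label = "study") {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(snp_ids)) snp_ids <- G$snp_meta$id
  Gs <- subset_snps(G, snp_ids)
  if (length(phenotype) != nrow(Gs$dosages)) {
    stop("phenotype length does not match the cohort", call. = FALSE)
  }
  mad <- minor_allele_dosages(Gs)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  out <- vector("list", ncol(mad$dosages))
  for (j in seq_len(ncol(mad$dosages))) {
    st <- logistic_assoc(phenotype, mad$dosages[, j], C)
    out[[j]] <- cbind(
      data.frame(snp_id = colnames(mad$dosages)[j],
                 study_label = study_label,
                 effect_allele = mad$effect_allele[j],
                 stringsAsFactors = FALSE),
      st[, c("effect", "se", "statistic", "p", "n_used", "flag")])
  }
  rec <- do.call(rbind, out)
  rec$or <- exp(rec$effect)
  rec$direction <- ifelse(is.na(rec$effect), NA_real_, sign(rec$effect))
  rec[, c("snp_id", "study_label", "effect_allele", "effect", "se",
          "statistic", "p", "or", "direction", "n_used", "flag")]
}

#' Fixed-effects meta-analysis across studies
#'
#' Harmonizes effect alleles across the per-study record lists (a study
#' whose record counts the complementary allele has its effect sign
#' flipped), then combines each SNP's non-degenerate study effects by
#' inverse-variance weighting (or weighted-Z, per `method`). SNPs absent
#' from every study are omitted.
#'
#' @param study_records List of per-study data frames from [run_gwas()].
#' @param method `"ivw"` or `"stouffer"`.
#' @return Data frame of meta records: `snp_id`, `effect_allele`,
#'   `effect`, `se`, `statistic`, `p`, `or`, `direction`, `n_studies`,
#'   `flag`.
#' @export
run_meta <- function(study_records, method = c("ivw", "stouffer")) {
  method <- match.arg(method)
  stopifnot(is.list(study_records), length(study_records) >= 1L)
  all_rec <- do.call(rbind, study_records)
  snps <- unique(all_rec$snp_id)
  combine <- if (method == "ivw") fixed_effects_meta else stouffer_meta
  out <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    rows <- all_rec[all_rec$snp_id == snps[i] & is.finite(all_rec$effect) &
                      is.finite(all_rec$se) & !is.na(all_rec$p), ,
                    drop = FALSE]
    if (nrow(rows) == 0L) {
      out[[i]] <- data.frame(
        snp_id = snps[i], effect_allele = NA_character_, effect = NA_real_,
        se = NA_real_, statistic = NA_real_, p = NA_real_, or = NA_real_,
        direction = NA_real_, n_studies = 0L, flag = "degenerate",
        stringsAsFactors = FALSE)
      next
    }
    # harmonize to the first study's effect allele
    ref_allele <- rows$effect_allele[1]
    flip <- rows$effect_allele != ref_allele
    eff <- ifelse(flip, -rows$effect, rows$effect)
    m <- combine(eff, rows$se)
    out[[i]] <- data.frame(
      snp_id = snps[i], effect_allele = ref_allele, effect = m$effect,
      se = m$se, statistic = m$statistic, p = m$p, or = exp(m$effect),
      direction = if (is.na(m$effect)) NA_real_ else sign(m$effect),
      n_studies = m$n_studies, flag = m$flag, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bonferroni prioritization over the eQTL SNP set
#'
#' The heart of the two-stage design: instead of a genome-wide correction,
#' the disease lookup is corrected only for the number of significant
#' eQTL SNPs, so the threshold is `fwer_alpha / n_eqtl_snps` — far more
#' permissive than a genome-wide Bonferroni while still controlling the
#' family-wise error over the tested set.
#'
#' @param eqtl_snp_ids Character vector of unique significant eQTL SNPs.
#' @param combined_records Data frame from [run_gwas()] on the combined
#'   (pooled mega-analysis) cohort.
#' @param fwer_alpha Family-wise alpha.
#' @return List: `threshold`, `n_tests`, and `significant` (the records of
#'   SNPs with `p < threshold`, ordered by p).
#' @export
prioritize_bonferroni <- function(eqtl_snp_ids, combined_records,
                                  fwer_alpha = 0.05) {
  if (length(eqtl_snp_ids) == 0L) {
    stop("empty eQTL SNP set: nothing to prioritize", call. = FALSE)
  }
  thr <- bonferroni_threshold(fwer_alpha, length(eqtl_snp_ids))
  rec <- combined_records[combined_records$snp_id %in% eqtl_snp_ids, ,
                          drop = FALSE]
  sig <- rec[!is.na(rec$p) & rec$p < thr, , drop = FALSE]
  sig <- sig[order(sig$p), , drop = FALSE]
  rownames(sig) <- NULL
  list(threshold = thr, n_tests = length(eqtl_snp_ids), significant = sig)
}

#' Nominal candidate union of combined and meta analyses
#'
#' Takes the union of SNPs reaching `p < nominal_p` in either the pooled
#' (combined) analysis or the meta-analysis, recording the provenance of
#' each member; SNPs already established (e.g. Bonferroni-significant
#' hits that are not retested) can be excluded.
#'
#' @param combined_records Data frame from [run_gwas()] (pooled cohort).
#' @param meta_records Data frame from [run_meta()].
#' @param nominal_p Nominal threshold.
#' @param exclude Character vector of SNP ids to drop from the candidate
#'   set.
#' @return Data frame: `snp_id`, `provenance` (`"combined"`, `"meta"` or
#'   `"both"`), `p_combined`, `p_meta`, `direction_combined`.
#' @export
select_nominal_candidates <- function(combined_records, meta_records,
                                      nominal_p = 0.01,
                                      exclude = character()) {
  hit_c <- combined_records$snp_id[!is.na(combined_records$p) &
                                     combined_records$p < nominal_p]
  hit_m <- meta_records$snp_id[!is.na(meta_records$p) &
                                 meta_records$p < nominal_p]
  ids <- setdiff(union(hit_c, hit_m), exclude)
  if (!length(ids)) {
    return(data.frame(snp_id = character(), provenance = character(),
                      p_combined = numeric(), p_meta = numeric(),
                      direction_combined = numeric(),
                      stringsAsFactors = FALSE))
  }
  prov <- ifelse(ids %in% hit_c & ids %in% hit_m, "both",
                 ifelse(ids %in% hit_c, "combined", "meta"))
  ci <- match(ids, combined_records$snp_id)
  mi <- match(ids, meta_records$snp_id)
  out <- data.frame(
    snp_id = ids, provenance = prov,
    p_combined = combined_records$p[ci],
    p_meta = meta_records$p[mi],
    direction_combined = combined_records$direction[ci],
    stringsAsFactors = FALSE)
  out <- out[order(pmin(out$p_combined, out$p_meta, na.rm = TRUE)), ]
  rownames(out) <- NULL
  out
}

#' Sequential two-cohort replication screen
#'
#' Pass 1 requires `p < replication_p` in the first (larger) screen
#' cohort; pass 2 additionally requires `p < replication_p` in the second
#' cohort with, by default, effect direction consistent between the two
#' screens and with the discovery analysis. Candidates absent from a
#' screen are reported as untested, never as failures.
#'
#' @param candidates Data frame from [select_nominal_candidates()] (needs
#'   `snp_id`; `direction_combined` is used for discovery-direction
#'   consistency when present).
#' @param screen1_records,screen2_records Per-study association data
#'   frames with at least `snp_id`, `p`, `direction` (as produced by
#'   [run_gwas()], or assembled from externally supplied per-study
#'   summaries, e.g. a family-based analysis).
#' @param replication_p Per-cohort screen threshold.
#' @param require_direction Require sign consistency for replication.
#' @return Data frame, one row per candidate: `snp_id`, `p_screen1`,
#'   `direction_screen1`, `p_screen2`, `direction_screen2`, `tested`,
#'   `pass_screen1`, `consistent_direction`, `replicated`.
#' @export
replication_screen <- function(candidates, screen1_records, screen2_records,
                               replication_p = 0.1,
                               require_direction = TRUE) {
  ids <- candidates$snp_id
  i1 <- match(ids, screen1_records$snp_id)
  i2 <- match(ids, screen2_records$snp_id)
  p1 <- screen1_records$p[i1]
  d1 <- screen1_records$direction[i1]
  p2 <- screen2_records$p[i2]
  d2 <- screen2_records$direction[i2]
  dd <- if ("direction_combined" %in% names(candidates)) {
    candidates$direction_combined
  } else {
    rep(NA_real_, length(ids))
  }
  tested <- !is.na(p1) & !is.na(p2)
  pass1 <- tested & p1 < replication_p
  consistent <- tested & d1 == d2 & (is.na(dd) | d1 == dd)
  replicated <- pass1 & p2 < replication_p &
    (if (require_direction) consistent else TRUE)
  data.frame(
    snp_id = ids, p_screen1 = p1, direction_screen1 = d1,
    p_screen2 = p2, direction_screen2 = d2, tested = tested,
    pass_screen1 = pass1, consistent_direction = consistent,
    replicated = replicated, stringsAsFactors = FALSE)
}
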