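#' Filter probes to annotated autosomal genes
#'
#' Keeps probes that carry a nonempty gene symbol and do not map to the X
#' or Y chromosome; input order is preserved.
#'
#' @param annotation Probe annotation data frame (`probe_id`,
#'   `gene_symbol`, `chrom`, `tss`, `strand`).
#' @return The filtered annotation data frame.
#' @export
filter_probes <- function(annotation) {
  sym <- annotation$gene_symbol
  has_gene <- !is.na(sym) & trimws(sym) != ""
  chrom <- sub("^chr", "", as.character(annotation$chrom))
  autosomal <- !(toupper(chrom) %in% c("X", "Y"))
  out <- annotation[has_gene & autosomal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter SNPs by minor allele frequency
#'
#' Keeps SNPs whose MAF, computed on the supplied cohort (the expression
#' cohort in the pipeline), is at least `maf_min`; SNPs strictly below the
#' threshold are excluded, so the boundary value survives.
#'
#' @param G A [genotype_matrix()].
#' @param maf_min MAF floor.
#' @return Character vector of kept SNP ids, in panel order.
#' @export
filter_snps <- function(G, maf_min) {
  stopifnot(inherits(G, "genotype_matrix"))
  maf <- apply(G$dosages, 2, function(d) {
    if (all(is.na(d))) NA_real_ else compute_maf(d)
  })
  G$snp_meta$id[!is.na(maf) & maf >= maf_min]
}

#' Enumerate cis SNP-probe pairs
#'
#' A pair is cis when the SNP and the probe's TSS share a chromosome and
#' `|pos - tss| <= window_bp` (inclusive boundary). Distance is signed and
#' strand-oriented: positive downstream of the TSS in the direction of
#' transcription (for minus-strand genes, `tss - pos`).
#'
#' @param snp_meta SNP metadata data frame (`id`, `chrom`, `pos`).
#' @param annotation Probe annotation data frame.
#' @param window_bp Cis window in bp.
#' @return Data frame `snp_id`, `probe_id`, `distance`, ordered by
#'   (chromosome, TSS, probe id, SNP position, SNP id).
#' @export
enumerate_cis_pairs <- function(snp_meta, annotation, window_bp) {
  stopifnot(window_bp > 0)
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    hits <- which(snp_meta$chrom == annotation$chrom[i] &
                    abs(snp_meta$pos - annotation$tss[i]) <= window_bp)
    if (!length(hits)) next
    sgn <- if (identical(annotation$strand[i], "-")) -1 else 1
    out[[i]] <- data.frame(
      snp_id = snp_meta$id[hits],
      probe_id = annotation$probe_id[i],
      distance = sgn * (snp_meta$pos[hits] - annotation$tss[i]),
      chrom = annotation$chrom[i], tss = annotation$tss[i],
      pos = snp_meta$pos[hits], stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pairs)) {
    return(data.frame(snp_id = character(), probe_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  pairs <- pairs[order(pairs$chrom, pairs$tss, pairs$probe_id, pairs$pos,
                       pairs$snp_id), ]
  rownames(pairs) <- NULL
  pairs[, c("snp_id", "probe_id", "distance")]
}

#' Run the covariate-adjusted cis-eQTL scan
#'
#' Fits one general linear model per SNP-probe pair — expression on
#' dosage, adjusted for the supplied covariates (in the pipeline: age, sex
#' and the genotype ancestry PCs) — and adjusts the raw p-values once,
#' jointly over all tested pairs, by Benjamini-Hochberg. Degenerate tests
#' (rank-deficient designs, e.g. a zero-variance SNP) are carried through
#' with their flag but excluded from the FDR input.
#'
#' @param G A [genotype_matrix()] of the expression cohort.
#' @param E An [expression_matrix()] aligned to the same samples.
#' @param covariates Numeric matrix / data frame of covariate columns
#'   aligned to the samples (or `NULL`).
#' @param pairs Cis pair data frame from [enumerate_cis_pairs()].
#' @param cfg A [pipeline_config()] (only reads fine-grained options; FDR
#'   level is applied later by [summarize_eqtls()]).
#' @return Data frame of eQTL records: `snp_id`, `probe_id`, `gene_symbol`,
#'   `chrom`, `pos`, `distance`, `effect`, `se`, `statistic`, `p`, `df`,
#'   `n_used`, `flag`, `fdr_p`.
#' @export
run_cis_scan <- function(G, E, covariates, pairs, cfg = pipeline_config()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(E, "expression_matrix"))
  if (!identical(G$sample_ids, E$sample_ids)) {
    stop("genotype and expression cohorts must contain the same samples ",
         "in the same order", call. = FALSE)
  }
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n_pairs <- nrow(pairs)
  if (n_pairs == 0L) {
    return(data.frame(snp_id = character(), probe_id = character(),
                      gene_symbol = character(), chrom = character(),
                      pos = numeric(), distance = numeric(),
                      effect = numeric(), se = numeric(),
                      statistic = numeric(), p = numeric(), df = numeric(),
                      n_used = integer(), flag = character(),
                      fdr_p = numeric(), stringsAsFactors = FALSE))
  }
  stats_list <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    g <- G$dosages[, pairs$snp_id[i]]
    y <- E$values[, pairs$probe_id[i]]
    stats_list[[i]] <- ols_assoc(y, g, C)
  }
  st <- do.call(rbind, stats_list)
  meta_idx <- match(pairs$snp_id, G$snp_meta$id)
  ann_idx <- match(pairs$probe_id, E$annotation$probe_id)
  rec <- data.frame(
    snp_id = pairs$snp_id, probe_id = pairs$probe_id,
    gene_symbol = E$annotation$gene_symbol[ann_idx],
    chrom = G$snp_meta$chrom[meta_idx], pos = G$snp_meta$pos[meta_idx],
    distance = pairs$distance,
    effect = st$effect, se = st$se, statistic = st$statistic, p = st$p,
    df = st$df, n_used = st$n_used, flag = st$flag,
    fdr_p = NA_real_, stringsAsFactors = FALSE)
  ok <- !is.na(rec$p)
  if (any(ok)) rec$fdr_p[ok] <- bh_adjust(rec$p[ok])
  rec
}

#' Summarize a cis-eQTL scan
#'
#' Counts significant records at an FDR threshold and reports the implied
#' raw-p cutoff (the largest raw p-value among significant pairs).
#'
#' @param records eQTL record data frame from [run_cis_scan()].
#' @param fdr_alpha FDR significance level.
#' @return List: `n_tests` (non-degenerate tests), `n_significant_pairs`,
#'   `n_unique_snps`, `n_unique_probes`, `n_unique_genes`,
#'   `max_raw_p_among_significant` (`NA` when nothing is significant).
#' @export
summarize_eqtls <- function(records, fdr_alpha = 0.05) {
  sig <- !is.na(records$fdr_p) & records$fdr_p < fdr_alpha
  list(
    n_tests = sum(!is.na(records$p)),
    n_significant_pairs = sum(sig),
    n_unique_snps = length(unique(records$snp_id[sig])),
    n_unique_probes = length(unique(records$probe_id[sig])),
    n_unique_genes = length(unique(records$gene_symbol[sig])),
    max_raw_p_among_significant =
      if (any(sig)) max(records$p[sig]) else NA_real_
  )
}
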