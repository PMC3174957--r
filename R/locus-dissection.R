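#' Pairwise LD r-squared matrix
#'
#' Squared pairwise-complete Pearson correlations of dosages for a SNP
#' set; the diagonal is 1 and the matrix is symmetric. Monomorphic SNPs
#' get `NA` rows/columns (their LD is undefined).
#'
#' @param G A [genotype_matrix()].
#' @param snp_ids SNPs to include (default: all).
#' @return Symmetric numeric matrix with SNP ids as dimnames.
#' @export
pairwise_r2 <- function(G, snp_ids = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(snp_ids)) snp_ids <- G$snp_meta$id
  M <- subset_snps(G, snp_ids)$dosages
  v <- apply(M, 2, stats::var, na.rm = TRUE)
  R <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))^2
  mono <- !is.na(v) & v == 0
  R[mono, ] <- NA_real_
  R[, mono] <- NA_real_
  diag(R)[!mono] <- 1
  R
}

#' Assign SNPs to tag-SNP LD bins
#'
#' Each tag SNP anchors a bin (assigned to itself with r^2 = 1). Every
#' other SNP joins the bin of the tag with which it has maximal r^2,
#' provided that r^2 reaches `ld_bin_r2_min`; otherwise, if its best tag
#' r^2 falls inside `moderate_ld_range` (half-open, lower bound
#' inclusive), it is placed in that tag's moderate-LD sub-bin; otherwise
#' it stays unbinned. Ties are broken toward the tag at the smaller
#' genomic position.
#'
#' @param r2_matrix Symmetric r^2 matrix from [pairwise_r2()] whose
#'   dimnames are SNP ids.
#' @param tags Data frame with columns `bin_label`, `snp_id`; labels must
#'   be unique and every tag must appear in the matrix.
#' @param positions Named numeric vector of genomic positions (for tie
#'   breaking); defaults to matrix order.
#' @param cfg A [pipeline_config()] supplying `ld_bin_r2_min` and
#'   `moderate_ld_range`.
#' @return A list of class `"ld_bin_table"`: `tags` and `assignments`
#'   (data frame `snp_id`, `bin_label`, `r2_to_tag`, `membership` in
#'   `{"tag", "core", "sub", "unbinned"}`).
#' @export
assign_ld_bins <- function(r2_matrix, tags, positions = NULL,
                           cfg = pipeline_config()) {
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)
  stopifnot(all(c("bin_label", "snp_id") %in% names(tags)))
  if (anyDuplicated(tags$bin_label) || anyDuplicated(tags$snp_id)) {
    stop("invalid config: duplicate tag labels or tag SNPs", call. = FALSE)
  }
  snps <- rownames(r2_matrix)
  if (!all(tags$snp_id %in% snps)) {
    stop("tags must be members of the SNP set", call. = FALSE)
  }
  if (is.null(positions)) {
    positions <- stats::setNames(seq_along(snps), snps)
  }
  r2min <- cfg$ld_bin_r2_min
  mod <- cfg$moderate_ld_range
  tag_pos_order <- order(positions[tags$snp_id])
  assignments <- data.frame(
    snp_id = snps, bin_label = NA_character_, r2_to_tag = NA_real_,
    membership = "unbinned", stringsAsFactors = FALSE)
  for (i in seq_along(snps)) {
    s <- snps[i]
    ti <- match(s, tags$snp_id)
    if (!is.na(ti)) {
      assignments$bin_label[i] <- tags$bin_label[ti]
      assignments$r2_to_tag[i] <- 1
      assignments$membership[i] <- "tag"
      next
    }
    r2 <- r2_matrix[s, tags$snp_id]
    if (all(is.na(r2))) next
    best <- max(r2, na.rm = TRUE)
    # tie toward the tag with the smaller genomic position
    cand <- which(!is.na(r2) & r2 == best)
    cand <- cand[order(match(cand, tag_pos_order))][1]
    if (best >= r2min) {
      assignments$bin_label[i] <- tags$bin_label[cand]
      assignments$r2_to_tag[i] <- best
      assignments$membership[i] <- "core"
    } else if (best >= mod[1] && best < mod[2]) {
      assignments$bin_label[i] <- paste0(tags$bin_label[cand], "_sub")
      assignments$r2_to_tag[i] <- best
      assignments$membership[i] <- "sub"
    }
  }
  structure(list(tags = tags, assignments = assignments,
                 ld_bin_r2_min = r2min, moderate_ld_range = mod),
            class = "ld_bin_table")
}

#' @export
print.ld_bin_table <- function(x, ...) {
  tab <- table(x$assignments$bin_label, useNA = "ifany")
  cat(sprintf("ld_bin_table: %d tags, %d SNPs (%d unbinned)\n",
              nrow(x$tags), nrow(x$assignments),
              sum(x$assignments$membership == "unbinned")))
  print(tab)
  invisible(x)
}

#' Per-SNP locus summary joining eQTL, LD-bin and disease evidence
#'
#' For every SNP of a locus interval, joins its position, its eQTL
#' p-value for each requested gene, its LD-bin assignment and its disease
#' association p-value — the table on which cross-bin inference rests
#' (e.g. noticing that two genes' eQTL SNPs occupy bins that are not in
#' LD with each other). Rows are ordered by position.
#'
#' @param interval List or vector with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param G A [genotype_matrix()].
#' @param eqtl_records eQTL records from [run_cis_scan()].
#' @param genes Character vector of gene symbols whose eQTL p-values
#'   become columns; genes with no probe in the records are dropped with
#'   a warning.
#' @param gwas_records Association records from [run_gwas()] (or `NULL`).
#' @param bins An `"ld_bin_table"` from [assign_ld_bins()] (or `NULL`).
#' @return Data frame with one row per locus SNP: `snp_id`, `pos`,
#'   one `eqtl_p_<gene>` column per gene (the minimum p over that gene's
#'   probes), `bin_label`, `r2_to_tag`, `gwas_p`.
#' @export
locus_summary_table <- function(interval, G, eqtl_records, genes,
                                gwas_records = NULL, bins = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  iv <- as.list(interval)
  sel <- G$snp_meta$chrom == as.character(iv$chrom) &
    G$snp_meta$pos >= as.numeric(iv$start) &
    G$snp_meta$pos <= as.numeric(iv$end)
  meta <- G$snp_meta[sel, , drop = FALSE]
  meta <- meta[order(meta$pos), , drop = FALSE]
  out <- data.frame(snp_id = meta$id, pos = meta$pos,
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(out)
  for (gene in genes) {
    rec <- eqtl_records[eqtl_records$gene_symbol == gene &
                          !is.na(eqtl_records$p), , drop = FALSE]
    if (nrow(rec) == 0L) {
      warning("no probe with eQTL records for gene ", gene,
              "; column omitted")
      next
    }
    p <- vapply(out$snp_id, function(s) {
      ps <- rec$p[rec$snp_id == s]
      if (length(ps)) min(ps) else NA_real_
    }, numeric(1))
    out[[paste0("eqtl_p_", gene)]] <- unname(p)
  }
  if (!is.null(bins)) {
    bi <- match(out$snp_id, bins$assignments$snp_id)
    out$bin_label <- bins$assignments$bin_label[bi]
    out$r2_to_tag <- bins$assignments$r2_to_tag[bi]
  }
  if (!is.null(gwas_records)) {
    gi <- match(out$snp_id, gwas_records$snp_id)
    out$gwas_p <- gwas_records$p[gi]
  }
  rownames(out) <- NULL
  out
}
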