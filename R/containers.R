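#' Construct a genotype matrix object
#'
#' Samples-by-SNPs additive dosage container with per-SNP metadata.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns, values
#'   in `{0, 1, 2}` or `NA`.
#' @param snp_meta Data frame with columns `id`, `chrom`, `pos` (1-based
#'   bp), `ref`, `alt`; one row per SNP, ids unique, positions strictly
#'   increasing within each chromosome.
#' @param sample_ids Character vector of unique sample ids (defaults to
#'   `rownames(dosages)` or `S1..Sn`).
#' @return A list of class `"genotype_matrix"` with elements `dosages`,
#'   `snp_meta`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, snp_meta, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  stopifnot(
    ncol(dosages) == nrow(snp_meta),
    all(c("id", "chrom", "pos", "ref", "alt") %in% names(snp_meta)),
    length(sample_ids) == nrow(dosages)
  )
  if (anyDuplicated(snp_meta$id)) stop("SNP ids must be unique", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique", call. = FALSE)
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(snp_meta$chrom)) {
    pos <- snp_meta$pos[snp_meta$chrom == ch]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("positions must be strictly increasing within a chromosome",
           call. = FALSE)
    }
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_meta$id
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  rownames(snp_meta) <- NULL
  structure(list(dosages = dosages, snp_meta = snp_meta,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$snp_meta$chrom), collapse = ", ")))
  invisible(x)
}

# Accept either a genotype_matrix or a bare samples x SNPs matrix.
dosage_matrix <- function(G) {
  if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
}

#' Subset a genotype matrix by SNP id
#'
#' @param G A `genotype_matrix`.
#' @param snp_ids SNP ids to keep (order preserved as given).
#' @return A `genotype_matrix` restricted to those SNPs.
#' @export
subset_snps <- function(G, snp_ids) {
  stopifnot(inherits(G, "genotype_matrix"))
  idx <- match(snp_ids, G$snp_meta$id)
  if (anyNA(idx)) {
    stop("unknown SNP ids: ",
         paste(snp_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  meta <- G$snp_meta[idx, , drop = FALSE]
  ord <- order(match(meta$chrom, unique(meta$chrom)), meta$pos)
  idx <- idx[ord]
  genotype_matrix(G$dosages[, idx, drop = FALSE],
                  G$snp_meta[idx, , drop = FALSE], G$sample_ids)
}

#' Minor-allele-oriented dosages
#'
#' Flips each SNP column so the counted allele is the minor allele in the
#' supplied cohort: columns whose ALT frequency exceeds 0.5 become
#' `2 - dosage`.
#'
#' @param G A `genotype_matrix` or dosage matrix.
#' @return A list with `dosages` (flipped matrix) and `effect_allele`
#'   (character vector, per SNP, the allele the dosage now counts; `alt`
#'   where no flip occurred, `ref` otherwise). For a bare matrix the
#'   alleles are reported as `"alt"`/`"ref"` labels.
#' @export
minor_allele_dosages <- function(G) {
  M <- dosage_matrix(G)
  f_alt <- colMeans(M, na.rm = TRUE) / 2
  flip <- !is.na(f_alt) & f_alt > 0.5
  M[, flip] <- 2 - M[, flip, drop = FALSE]
  if (inherits(G, "genotype_matrix")) {
    allele <- ifelse(flip, G$snp_meta$ref, G$snp_meta$alt)
  } else {
    allele <- ifelse(flip, "ref", "alt")
  }
  list(dosages = M, effect_allele = allele, flipped = flip)
}

#' Construct an expression matrix object
#'
#' @param values Samples-by-probes numeric matrix (normalized, log scale).
#' @param annotation Probe annotation data frame with columns `probe_id`,
#'   `gene_symbol`, `chrom`, `tss` (1-based bp), `strand` (`"+"`/`"-"`);
#'   probe ids unique, one row per probe column.
#' @param sample_ids Character sample ids (default from rownames).
#' @return A list of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, annotation, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  stopifnot(
    ncol(values) == nrow(annotation),
    all(c("probe_id", "gene_symbol", "chrom", "tss", "strand") %in%
          names(annotation)),
    all(annotation$tss >= 1)
  )
  if (anyDuplicated(annotation$probe_id)) {
    stop("probe ids must be unique", call. = FALSE)
  }
  rownames(values) <- sample_ids
  colnames(values) <- annotation$probe_id
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  rownames(annotation) <- NULL
  structure(list(values = values, annotation = annotation,
                 sample_ids = sample_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d probes (%d genes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$annotation$gene_symbol))))
  invisible(x)
}
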