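# Genotype readers/writers. Coordinates are 1-based inclusive throughout
# (VCF convention); the dosage-TSV dialect is one SNP per row with columns
# (id, chrom, pos, ref, alt, <one column per sample>).

gt_to_dosage <- function(gt) {
  # "0/0","0|1","1/1" -> 0,1,2; "./.", ".", haploid -> NA
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2L || any(alleles == ".")) return(NA_real_)
  suppressWarnings(sum(as.numeric(alleles) > 0))
}

#' Read a genotype matrix from VCF or dosage TSV
#'
#' VCF GT fields are converted to ALT-allele dosage; missing (`./.`),
#' haploid and multi-allelic records become missing values with a warning.
#' (Minor-allele orientation, which depends on the analyzed cohort, is
#' applied downstream by [minor_allele_dosages()] / [run_gwas()].) The TSV
#' dialect is one SNP per row: `id`, `chrom`, `pos`, `ref`, `alt`, then
#' one dosage column per sample.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "tsv"
    }
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) set to missing")
  }
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  dos[multi, ] <- NA_real_
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  meta <- data.frame(id = ids, chrom = fix$CHROM,
                     pos = as.numeric(fix$POS), ref = fix$REF,
                     alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(t(dos), meta, colnames(gt))
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    stop("dosage TSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sample_cols <- setdiff(names(tab), need)
  if (!length(sample_cols)) stop("dosage TSV has no sample columns",
                                 call. = FALSE)
  dos <- t(as.matrix(tab[, sample_cols, drop = FALSE]))
  bad <- which(!is.na(dos) & !(dos %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed dosage at SNP row %d (file line %d)",
                 bad[1, 2], bad[1, 2] + 1L), call. = FALSE)
  }
  meta <- data.frame(id = as.character(tab$id),
                     chrom = as.character(tab$chrom),
                     pos = as.numeric(tab$pos),
                     ref = as.character(tab$ref),
                     alt = as.character(tab$alt), stringsAsFactors = FALSE)
  genotype_matrix(dos, meta, sample_cols)
}

#' Write a genotype matrix
#'
#' `write_genotypes_tsv()` writes the dosage-TSV dialect;
#' `write_genotypes_vcf()` writes a minimal VCFv4.2 file with GT fields
#' (`0/0`, `0/1`, `1/1`, `./.`). Both round-trip exactly through
#' [read_genotypes()].
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  tab <- cbind(G$snp_meta, as.data.frame(t(G$dosages)))
  names(tab) <- c(names(G$snp_meta), G$sample_ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(G$snp_meta)), function(i) {
    d <- G$dosages[, i]
    gts <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(G$snp_meta$chrom[i], G$snp_meta$pos[i], G$snp_meta$id[i],
            G$snp_meta$ref[i], G$snp_meta$alt[i], ".", "PASS", ".", "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
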