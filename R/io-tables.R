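# TSV readers/writers for expression, annotation, covariates and stage
# outputs, plus the JSON run manifest. p-values and effects are written at
# full precision (scientific notation where needed).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", ...)
}

#' Write / read an expression matrix
#'
#' TSV with a `sample_id` column followed by one column per probe; the
#' probe annotation travels in a companion annotation file (see
#' [write_annotation()]).
#'
#' @param E An [expression_matrix()].
#' @param path Output path.
#' @return `path` (writer) / an [expression_matrix()] (reader).
#' @export
write_expression <- function(E, path) {
  stopifnot(inherits(E, "expression_matrix"))
  df <- data.frame(sample_id = E$sample_ids, E$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(format(df, digits = 17, trim = TRUE, scientific = NA), path)
}

#' @rdname write_expression
#' @param annotation Probe annotation data frame (or path to one) used to
#'   rebuild the object.
#' @export
read_expression <- function(path, annotation) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  tab <- read_tsv(path)
  if (!"sample_id" %in% names(tab)) {
    stop("expression TSV must contain a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample ids in expression file", call. = FALSE)
  }
  vals <- as.matrix(tab[, setdiff(names(tab), "sample_id"), drop = FALSE])
  probes <- colnames(vals)
  ann <- annotation[match(probes, annotation$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id)) {
    stop("expression probes missing from annotation: ",
         paste(probes[is.na(ann$probe_id)], collapse = ", "), call. = FALSE)
  }
  expression_matrix(vals, ann, as.character(tab$sample_id))
}

#' Write / read probe annotation
#'
#' Columns `probe_id`, `gene_symbol`, `chrom`, `tss`, `strand`;
#' coordinates are 1-based inclusive (stated in the file's comment
#' header). Empty gene symbols are preserved as empty strings so
#' [filter_probes()] sees them.
#'
#' @param annotation Annotation data frame.
#' @param path File path.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# probe annotation; tss is 1-based inclusive bp", con)
  utils::write.table(annotation, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  tab <- read_tsv(path, colClasses = c(gene_symbol = "character"))
  need <- c("probe_id", "gene_symbol", "chrom", "tss", "strand")
  if (!all(need %in% names(tab))) {
    stop("annotation TSV must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$probe_id)) {
    stop("duplicate probe ids in annotation", call. = FALSE)
  }
  tab$gene_symbol[is.na(tab$gene_symbol)] <- ""
  tab$chrom <- as.character(tab$chrom)
  tab$tss <- as.numeric(tab$tss)
  tab
}

#' Write / read a covariate table
#'
#' Columns `sample_id`, `age`, `sex` (0 = female, 1 = male; stated in the
#' comment header), `pack_years`, and optionally `status`, `study`.
#'
#' @param covariates Covariate data frame.
#' @param path File path.
#' @export
write_covariates <- function(covariates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# covariates; sex: 0 = female, 1 = male", con)
  utils::write.table(covariates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  tab <- read_tsv(path)
  if (!"sample_id" %in% names(tab)) {
    stop("covariate TSV must contain a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample ids in covariates", call. = FALSE)
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab
}

#' Align covariates to a genotype cohort
#'
#' Matches covariate rows to the cohort's sample ids; unmatched ids on
#' either side are reported with a warning and returned so a run manifest
#' can record them.
#'
#' @param covariates Covariate data frame with `sample_id`.
#' @param sample_ids Character cohort sample ids.
#' @return List: `covariates` (reordered to `sample_ids`, `NA` rows for
#'   cohort samples without covariates), `unmatched_covariates`,
#'   `unmatched_samples`.
#' @export
align_covariates <- function(covariates, sample_ids) {
  idx <- match(sample_ids, covariates$sample_id)
  unmatched_samples <- sample_ids[is.na(idx)]
  unmatched_covariates <- setdiff(covariates$sample_id, sample_ids)
  if (length(unmatched_samples)) {
    warning(length(unmatched_samples),
            " cohort sample(s) have no covariates")
  }
  if (length(unmatched_covariates)) {
    warning(length(unmatched_covariates),
            " covariate row(s) match no cohort sample")
  }
  out <- covariates[idx, , drop = FALSE]
  out$sample_id <- sample_ids
  rownames(out) <- NULL
  list(covariates = out, unmatched_covariates = unmatched_covariates,
       unmatched_samples = unmatched_samples)
}

#' Write a simulation truth table
#'
#' TSV with columns `kind` (`cis`/`disease`), `snp_id`, `probe_id`,
#' `effect` — the planted-effect registry that parameter-recovery tests
#' consume.
#'
#' @param truth Truth data frame from [generate_study_bundle()].
#' @param path File path.
#' @export
write_sim_truth <- function(truth, path) write_tsv(truth, path)

#' Write a run manifest
#'
#' JSON file capturing everything needed to replay a run: the
#' configuration snapshot, MD5 checksums of the input files, the package
#' version, the master seed and a timestamp. Exactly one manifest is
#' written per output directory.
#'
#' @param dir Output directory.
#' @param config A [pipeline_config()] (or any list) to snapshot.
#' @param inputs Named character vector of input file paths to checksum.
#' @param seed Master seed of the run.
#' @param extra Optional named list of additional fields (e.g. exclusion
#'   lists from [align_covariates()]).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, inputs = character(), seed = NA,
                           extra = list()) {
  manifest <- c(list(
    package = "eqtlpipe",
    version = as.character(utils::packageVersion("eqtlpipe")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = seed,
    config = unclass(config),
    input_checksums = if (length(inputs)) {
      as.list(tools::md5sum(unname(unlist(inputs))))
    } else {
      list()
    }
  ), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Write a study bundle to a directory
#'
#' Serializes every component through the package's paired writers:
#' genotypes as VCF, expression/annotation/covariates/phenotypes/truth as
#' TSV, plus a manifest. [read_study_inputs()] reads them back.
#'
#' @param bundle A `"study_bundle"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_vcf(bundle$genotypes,
                      file.path(dir, "expression_cohort.vcf"))
  write_expression(bundle$expression, file.path(dir, "expression.tsv"))
  write_annotation(bundle$annotation, file.path(dir, "annotation.tsv"))
  write_covariates(bundle$covariates,
                   file.path(dir, "expression_covariates.tsv"))
  for (st in bundle$studies) {
    write_genotypes_vcf(st$genotypes,
                        file.path(dir, paste0(st$label, ".vcf")))
    cov <- st$covariates
    cov$status <- st$phenotype[cov$sample_id]
    cov$study <- st$label
    write_covariates(cov, file.path(dir, paste0(st$label, "_covariates.tsv")))
  }
  write_sim_truth(bundle$truth, file.path(dir, "sim_truth.tsv"))
  write_manifest(dir, bundle$config,
                 seed = bundle$config$master_seed)
  invisible(dir)
}

#' Read bundle components back from a directory
#'
#' @param dir Directory written by [write_study_bundle()].
#' @return List with `genotypes`, `expression`, `annotation`,
#'   `covariates`, `studies` (each with `genotypes`, `covariates`,
#'   `phenotype`, `label`), `truth`.
#' @export
read_study_inputs <- function(dir) {
  annotation <- read_annotation(file.path(dir, "annotation.tsv"))
  genotypes <- read_genotypes(file.path(dir, "expression_cohort.vcf"))
  expression <- read_expression(file.path(dir, "expression.tsv"), annotation)
  covariates <- read_covariates(file.path(dir, "expression_covariates.tsv"))
  study_files <- list.files(dir, pattern = "^(discovery|replication)[0-9]+\\.vcf$")
  studies <- lapply(study_files, function(f) {
    label <- sub("\\.vcf$", "", f)
    G <- read_genotypes(file.path(dir, f))
    cov <- read_covariates(file.path(dir, paste0(label, "_covariates.tsv")))
    cov <- align_covariates(cov, G$sample_ids)$covariates
    list(label = label,
         role = sub("[0-9]+$", "", label),
         genotypes = G, covariates = cov,
         phenotype = stats::setNames(as.integer(cov$status),
                                     cov$sample_id))
  })
  names(studies) <- sub("\\.vcf$", "", study_files)
  truth_path <- file.path(dir, "sim_truth.tsv")
  truth <- if (file.exists(truth_path)) read_tsv(truth_path) else NULL
  list(genotypes = genotypes, expression = expression,
       annotation = annotation, covariates = covariates,
       studies = studies, truth = truth)
}

#' Read externally supplied two-cohort replication summaries
#'
#' Parses a TSV of per-SNP replication summary statistics (as produced by
#' external association engines, e.g. a family-based analysis for the
#' first screen) into the three tables [replication_screen()] consumes.
#' Expected columns: `snp_id`, `screen1_direction` (`Increase`/`Decrease`
#' or a sign), `screen1_p`, `screen2_or`, `screen2_p`, and optionally
#' `discovery_or`, `discovery_p`. An example dataset ships with the
#' package: `system.file("extdata", "replication_screen_example.tsv",
#' package = "eqtlpipe")`.
#'
#' @param path Path to the summary TSV.
#' @return List of data frames: `candidates` (with
#'   `direction_combined` from the discovery OR where available),
#'   `screen1`, `screen2`.
#' @export
read_replication_summaries <- function(path) {
  tab <- read_tsv(path)
  need <- c("snp_id", "screen1_direction", "screen1_p", "screen2_or",
            "screen2_p")
  if (!all(need %in% names(tab))) {
    stop("replication summary TSV must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  dir1 <- ifelse(grepl("^inc", tab$screen1_direction, ignore.case = TRUE), 1,
                 ifelse(grepl("^dec", tab$screen1_direction,
                              ignore.case = TRUE), -1,
                        sign(suppressWarnings(
                          as.numeric(tab$screen1_direction)))))
  dd <- if ("discovery_or" %in% names(tab)) {
    ifelse(is.na(tab$discovery_or), NA_real_, sign(log(tab$discovery_or)))
  } else {
    rep(NA_real_, nrow(tab))
  }
  list(
    candidates = data.frame(snp_id = tab$snp_id, direction_combined = dd,
                            stringsAsFactors = FALSE),
    screen1 = data.frame(snp_id = tab$snp_id, p = tab$screen1_p,
                         direction = dir1, stringsAsFactors = FALSE),
    screen2 = data.frame(snp_id = tab$snp_id, p = tab$screen2_p,
                         direction = sign(log(tab$screen2_or)),
                         stringsAsFactors = FALSE))
}
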