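#' Pipeline configuration
#'
#' Collects every tunable threshold of the two-stage analysis in one
#' validated object. Defaults reproduce the conventional settings for a
#' sputum-type cis-eQTL / COPD GWAS integration: a 50 kb cis window around
#' the TSS (expandable to 200 kb for candidate loci), a 5% minor allele
#' frequency floor, FDR 0.05 for eQTL significance, family-wise alpha 0.05
#' for the Bonferroni lookup over the reduced SNP set, nominal p < 0.01 for
#' the candidate union, p < 0.1 per cohort for the replication screen, six
#' genotype ancestry principal components, and LD bins built at r^2 >= 0.80
#' with moderate-LD sub-bins in (0.50, 0.80).
#'
#' @param cis_window_bp Window around the TSS (bp, inclusive) for cis pairs.
#' @param expanded_window_bp Expanded window used for candidate-locus rescans.
#' @param maf_min Minimum minor allele frequency; SNPs with MAF strictly
#'   below this are excluded (the boundary value is kept).
#' @param fdr_alpha FDR threshold declaring an eQTL significant.
#' @param fwer_alpha Family-wise alpha for the Bonferroni disease lookup.
#' @param nominal_p Nominal disease-association threshold for the candidate
#'   union (combined or meta analysis).
#' @param replication_p Per-cohort threshold of the sequential replication
#'   screen.
#' @param n_pcs Number of genotype principal components used as ancestry
#'   covariates.
#' @param ld_bin_r2_min Minimum r^2 to a tag SNP for core LD-bin membership.
#' @param moderate_ld_range Length-2 numeric, the half-open r^2 interval
#'   (low, high) defining moderate-LD sub-bins.
#' @param meta_method `"ivw"` (inverse-variance weighting on effects,
#'   default) or `"stouffer"` (weighted-Z combination).
#' @param require_direction Logical; must replication effects agree in sign
#'   with the first screen and the discovery analysis?
#' @param exclude_bonferroni_from_replication Logical; drop SNPs already
#'   Bonferroni-significant from the replication candidate set (they are
#'   considered established and are not retested).
#' @return A list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$cis_window_bp
pipeline_config <- function(cis_window_bp = 50000L,
                            expanded_window_bp = 200000L,
                            maf_min = 0.05,
                            fdr_alpha = 0.05,
                            fwer_alpha = 0.05,
                            nominal_p = 0.01,
                            replication_p = 0.1,
                            n_pcs = 6L,
                            ld_bin_r2_min = 0.80,
                            moderate_ld_range = c(0.50, 0.80),
                            meta_method = c("ivw", "stouffer"),
                            require_direction = TRUE,
                            exclude_bonferroni_from_replication = TRUE) {
  meta_method <- match.arg(meta_method)
  stopifnot(
    is.numeric(cis_window_bp), length(cis_window_bp) == 1L, cis_window_bp > 0,
    is.numeric(expanded_window_bp), expanded_window_bp > 0,
    length(moderate_ld_range) == 2L,
    moderate_ld_range[1] < moderate_ld_range[2]
  )
  for (nm in c("maf_min", "fdr_alpha", "fwer_alpha", "nominal_p",
               "replication_p", "ld_bin_r2_min")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop(sprintf("`%s` must be a single number in (0, 1)", nm),
           call. = FALSE)
    }
  }
  if (n_pcs < 0) stop("`n_pcs` must be >= 0", call. = FALSE)
  structure(list(
    cis_window_bp = as.numeric(cis_window_bp),
    expanded_window_bp = as.numeric(expanded_window_bp),
    maf_min = maf_min,
    fdr_alpha = fdr_alpha,
    fwer_alpha = fwer_alpha,
    nominal_p = nominal_p,
    replication_p = replication_p,
    n_pcs = as.integer(n_pcs),
    ld_bin_r2_min = ld_bin_r2_min,
    moderate_ld_range = as.numeric(moderate_ld_range),
    meta_method = meta_method,
    require_direction = isTRUE(require_direction),
    exclude_bonferroni_from_replication =
      isTRUE(exclude_bonferroni_from_replication)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected so typos fail loudly; missing keys take the
#' `pipeline_config()` defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file whose keys are
#'   arguments of [pipeline_config()].
#' @return A `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: ", ext, call. = FALSE)
  )
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

# Deterministic child seed for a named simulation stream. Streams are fixed
# small integers enumerated once per component, so adding a stage never
# perturbs the draws of earlier stages.
child_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(stream), length(stream) == 1L)
  as.integer((abs(as.double(master_seed)) * 48271 +
                as.double(stream) * 30269 + 12345) %% 2147483647)
}
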