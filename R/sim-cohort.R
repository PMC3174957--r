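# Covariate moments of the emulated cohort: mean age 65 (SD 5.5), 66% male,
# mean pack-years 47 (SD 28, truncated at 0).
.COV_MOMENTS <- list(age = c(mean = 65, sd = 5.5), sex_p = 0.66,
                     pack_years = c(mean = 47, sd = 28))

#' Simulate sample covariates
#'
#' Age ~ Normal(65, 5.5); sex ~ Bernoulli(0.66) coded 1 = male; pack-years
#' ~ Normal(47, 28) truncated at zero (rejection sampling, so no point mass
#' at 0).
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param sample_ids Optional character ids (default `S0001..`).
#' @return Data frame with columns `sample_id`, `age`, `sex`, `pack_years`.
#' @export
simulate_covariates <- function(n, seed, sample_ids = NULL) {
  set.seed(as.integer(seed))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  age <- stats::rnorm(n, .COV_MOMENTS$age["mean"], .COV_MOMENTS$age["sd"])
  sex <- stats::rbinom(n, 1L, .COV_MOMENTS$sex_p)
  py <- stats::rnorm(n, .COV_MOMENTS$pack_years["mean"],
                     .COV_MOMENTS$pack_years["sd"])
  while (any(py < 0)) {
    py[py < 0] <- stats::rnorm(sum(py < 0), .COV_MOMENTS$pack_years["mean"],
                               .COV_MOMENTS$pack_years["sd"])
  }
  data.frame(sample_id = sample_ids, age = age, sex = sex, pack_years = py,
             stringsAsFactors = FALSE)
}

#' Probe annotation for a simulated gene panel
#'
#' Places `n_genes` genes evenly along the SNP panel, one probe per gene,
#' each TSS at the position of a SNP near the centre of its slice (so cis
#' pairs always exist); strands alternate.
#'
#' @param snp_meta SNP metadata data frame (`id`, `chrom`, `pos`).
#' @param n_genes Number of genes.
#' @return Probe annotation data frame (`probe_id`, `gene_symbol`, `chrom`,
#'   `tss`, `strand`).
#' @export
simulate_annotation <- function(snp_meta, n_genes) {
  if (n_genes == 0L) {
    return(data.frame(probe_id = character(), gene_symbol = character(),
                      chrom = character(), tss = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  S <- nrow(snp_meta)
  anchor <- pmax(1L, pmin(S, round((seq_len(n_genes) - 0.5) / n_genes * S)))
  data.frame(
    probe_id = sprintf("probe%03d_at", seq_len(n_genes)),
    gene_symbol = sprintf("GENE%03d", seq_len(n_genes)),
    chrom = snp_meta$chrom[anchor],
    tss = snp_meta$pos[anchor],
    strand = rep(c("+", "-"), length.out = n_genes),
    stringsAsFactors = FALSE)
}

# Resolve user-facing cis_effects (snp by index or id, probe by index, id or
# NA = nearest TSS) against a concrete panel.
resolve_cis_effects <- function(cis_effects, snp_meta, annotation) {
  if (is.null(cis_effects) || nrow(cis_effects) == 0L) {
    return(data.frame(snp_id = character(), probe_id = character(),
                      beta = numeric(), stringsAsFactors = FALSE))
  }
  snp_id <- vapply(cis_effects$snp, function(s) {
    if (is.numeric(s)) snp_meta$id[as.integer(s)] else as.character(s)
  }, character(1))
  if (anyNA(snp_id) || !all(snp_id %in% snp_meta$id)) {
    stop("invalid config: planted cis SNP not on the panel", call. = FALSE)
  }
  probe_id <- character(nrow(cis_effects))
  for (i in seq_len(nrow(cis_effects))) {
    pr <- cis_effects$probe[i]
    if (is.na(pr)) {
      pos <- snp_meta$pos[snp_meta$id == snp_id[i]]
      ch <- snp_meta$chrom[snp_meta$id == snp_id[i]]
      cand <- annotation[annotation$chrom == ch, , drop = FALSE]
      if (nrow(cand) == 0L) stop("no probe on the planted SNP's chromosome",
                                 call. = FALSE)
      probe_id[i] <- cand$probe_id[which.min(abs(cand$tss - pos))]
    } else if (is.numeric(pr)) {
      probe_id[i] <- annotation$probe_id[as.integer(pr)]
    } else {
      probe_id[i] <- as.character(pr)
    }
  }
  if (anyNA(probe_id) || !all(probe_id %in% annotation$probe_id)) {
    stop("invalid config: planted probe not in the annotation", call. = FALSE)
  }
  data.frame(snp_id = snp_id, probe_id = probe_id,
             beta = as.numeric(cis_effects$beta), stringsAsFactors = FALSE)
}

resolve_disease_effects <- function(disease_log_odds, snp_meta) {
  if (is.null(disease_log_odds) || length(disease_log_odds) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  nm <- names(disease_log_odds)
  if (is.null(nm)) stop("disease_log_odds must be named", call. = FALSE)
  ids <- ifelse(grepl("^[0-9]+$", nm),
                snp_meta$id[as.integer(nm)], nm)
  if (anyNA(ids) || !all(ids %in% snp_meta$id)) {
    stop("invalid config: planted disease SNP not on the panel",
         call. = FALSE)
  }
  stats::setNames(as.numeric(disease_log_odds), ids)
}

#' Simulate probe-level expression with planted cis effects
#'
#' Generates `expression(sample, probe) = intercept + beta * dosage +
#' covariate terms + Normal(0, noise_sd)` on a log2-like scale. Covariates
#' enter centered at their generative means so the intercept is the
#' baseline expression of an average sample. Every planted SNP must lie
#' within `cis_window_bp` of its probe's TSS — a planted effect outside the
#' scan window would be undetectable by design and is rejected.
#'
#' @param G A [genotype_matrix()] for the expression cohort.
#' @param annotation Probe annotation data frame.
#' @param cis_effects Resolved or user-form cis effect table (see
#'   [sim_config()]).
#' @param covariates Covariate data frame from [simulate_covariates()]
#'   aligned to `G` (or `NULL`).
#' @param covariate_effects Named numeric vector of expression covariate
#'   effects (subset of `age`, `sex`, `pack_years`).
#' @param noise_sd Residual SD.
#' @param seed Integer seed for the noise draw.
#' @param intercept Baseline expression level.
#' @param cis_window_bp Window used to validate planted pairs.
#' @return List with `expression` (an [expression_matrix()]) and `truth`
#'   (data frame `kind`, `snp_id`, `probe_id`, `effect`).
#' @export
simulate_expression <- function(G, annotation, cis_effects = NULL,
                                covariates = NULL,
                                covariate_effects = c(age = 0.02, sex = 0.25),
                                noise_sd = 1, seed = 1L, intercept = 7,
                                cis_window_bp = 50000) {
  stopifnot(inherits(G, "genotype_matrix"))
  eff <- resolve_cis_effects(cis_effects, G$snp_meta, annotation)
  for (i in seq_len(nrow(eff))) {
    pos <- G$snp_meta$pos[G$snp_meta$id == eff$snp_id[i]]
    tss <- annotation$tss[annotation$probe_id == eff$probe_id[i]]
    if (abs(pos - tss) > cis_window_bp) {
      stop(sprintf(
        "invalid config: planted SNP %s is %d bp from the TSS of %s (window %d)",
        eff$snp_id[i], abs(pos - tss), eff$probe_id[i],
        as.integer(cis_window_bp)), call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  n <- nrow(G$dosages)
  P <- nrow(annotation)
  E <- matrix(intercept, nrow = n, ncol = P,
              dimnames = list(G$sample_ids, annotation$probe_id))
  cov_term <- covariate_linear_term(covariates, covariate_effects, n)
  E <- E + cov_term  # same covariate term for every probe
  for (i in seq_len(nrow(eff))) {
    g <- G$dosages[, eff$snp_id[i]]
    E[, eff$probe_id[i]] <- E[, eff$probe_id[i]] + eff$beta[i] * g
  }
  E <- E + matrix(stats::rnorm(n * P, sd = noise_sd), nrow = n)
  truth <- if (nrow(eff)) {
    data.frame(kind = "cis", snp_id = eff$snp_id, probe_id = eff$probe_id,
               effect = eff$beta, stringsAsFactors = FALSE)
  } else {
    data.frame(kind = character(), snp_id = character(),
               probe_id = character(), effect = numeric(),
               stringsAsFactors = FALSE)
  }
  list(expression = expression_matrix(E, annotation, G$sample_ids),
       truth = truth)
}

# Linear predictor contribution of covariates, centered at generative means.
covariate_linear_term <- function(covariates, covariate_effects, n) {
  term <- rep(0, n)
  if (is.null(covariates) || is.null(covariate_effects) ||
      length(covariate_effects) == 0L) {
    return(term)
  }
  centers <- c(age = unname(.COV_MOMENTS$age["mean"]),
               sex = .COV_MOMENTS$sex_p,
               pack_years = unname(.COV_MOMENTS$pack_years["mean"]))
  for (nm in names(covariate_effects)) {
    if (!nm %in% names(covariates)) {
      stop("covariate effect refers to missing column: ", nm, call. = FALSE)
    }
    ctr <- if (nm %in% names(centers)) centers[[nm]] else 0
    term <- term + covariate_effects[[nm]] * (covariates[[nm]] - ctr)
  }
  term
}

#' Simulate a binary phenotype under a logistic liability model
#'
#' `P(case) = plogis(baseline_log_odds + sum(gamma * dosage) + covariate
#' terms)`; covariates enter centered at their generative means.
#'
#' @param G A [genotype_matrix()].
#' @param disease_log_odds Named numeric per-allele log-odds (names are SNP
#'   ids or panel indices); may be empty.
#' @param covariates Covariate data frame aligned to `G` (or `NULL`).
#' @param covariate_effects Named numeric disease covariate effects.
#' @param baseline_log_odds Intercept of the liability.
#' @param seed Integer seed.
#' @return Integer 0/1 phenotype vector named by sample id.
#' @export
simulate_case_control <- function(G, disease_log_odds = NULL,
                                  covariates = NULL,
                                  covariate_effects = NULL,
                                  baseline_log_odds = 0, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  gam <- resolve_disease_effects(disease_log_odds, G$snp_meta)
  n <- nrow(G$dosages)
  eta <- rep(baseline_log_odds, n)
  for (id in names(gam)) eta <- eta + gam[[id]] * G$dosages[, id]
  eta <- eta + covariate_linear_term(covariates, covariate_effects, n)
  set.seed(as.integer(seed))
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  stats::setNames(as.integer(y), G$sample_ids)
}

#' Generate a complete multi-study simulation bundle
#'
#' Builds one shared SNP panel and haplotype pool, then draws from it an
#' expression cohort (genotypes, covariates, probe expression with planted
#' cis effects) and every discovery and replication case-control study
#' (genotypes, covariates, phenotypes with planted disease effects). Each
#' study's liability intercept is calibrated on its realized genotypes and
#' covariates so the expected case fraction matches the configured design.
#' All randomness descends from `cfg$master_seed` through fixed per-stage
#' child streams, so identical configurations give identical bundles.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"study_bundle"`: `pool`, `annotation`,
#'   `genotypes` (expression cohort), `covariates`, `expression`, `studies`
#'   (list with `label`, `role` = discovery/replication, `genotypes`,
#'   `covariates`, `phenotype`), `truth` (planted cis and disease effects),
#'   `config`.
#' @export
generate_study_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pool <- simulate_haplotype_pool(cfg)
  annotation <- simulate_annotation(pool$snp_meta, cfg$n_genes)
  gam <- resolve_disease_effects(cfg$disease_log_odds, pool$snp_meta)

  Ge <- simulate_genotypes(pool, cfg$n_expression_samples,
                           child_seed(cfg$master_seed, 2L),
                           sample_prefix = "E")
  cov_e <- simulate_covariates(cfg$n_expression_samples,
                               child_seed(cfg$master_seed, 3L),
                               sample_ids = Ge$sample_ids)
  expr <- simulate_expression(
    Ge, annotation, cfg$cis_effects, cov_e,
    cfg$covariate_effects$expression, cfg$noise_sd,
    seed = child_seed(cfg$master_seed, 4L))

  make_study <- function(size, label, role, stream0, prefix) {
    n <- sum(size)
    Gs <- simulate_genotypes(pool, n, child_seed(cfg$master_seed, stream0),
                             sample_prefix = prefix)
    cov_s <- simulate_covariates(n, child_seed(cfg$master_seed, stream0 + 1L),
                                 sample_ids = Gs$sample_ids)
    # calibrate the intercept so the expected case fraction hits the design
    eta0 <- rep(0, n)
    for (id in names(gam)) eta0 <- eta0 + gam[[id]] * Gs$dosages[, id]
    eta0 <- eta0 + covariate_linear_term(
      cov_s, cfg$covariate_effects$disease, n)
    frac <- size[1] / n
    baseline <- stats::qlogis(min(max(frac, 0.02), 0.98)) - mean(eta0)
    y <- simulate_case_control(Gs, gam, cov_s,
                               cfg$covariate_effects$disease,
                               baseline_log_odds = baseline,
                               seed = child_seed(cfg$master_seed,
                                                 stream0 + 2L))
    list(label = label, role = role, genotypes = Gs, covariates = cov_s,
         phenotype = y, target_size = size)
  }

  studies <- list()
  for (i in seq_along(cfg$study_sizes)) {
    studies[[length(studies) + 1L]] <- make_study(
      cfg$study_sizes[[i]], sprintf("discovery%d", i), "discovery",
      10L + 3L * i, sprintf("D%d_", i))
  }
  for (i in seq_along(cfg$replication_sizes)) {
    studies[[length(studies) + 1L]] <- make_study(
      cfg$replication_sizes[[i]], sprintf("replication%d", i), "replication",
      100L + 3L * i, sprintf("R%d_", i))
  }
  names(studies) <- vapply(studies, `[[`, character(1), "label")

  truth <- expr$truth
  if (length(gam)) {
    truth <- rbind(truth, data.frame(
      kind = "disease", snp_id = names(gam), probe_id = NA_character_,
      effect = unname(gam), stringsAsFactors = FALSE))
  }
  structure(list(pool = pool, annotation = annotation, genotypes = Ge,
                 covariates = cov_e, expression = expr$expression,
                 studies = studies, truth = truth, config = cfg),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "study_bundle: %d SNPs, %d genes; expression n=%d; %d studies (%s)\n",
    "planted effects: %d cis, %d disease\n"),
    x$config$n_snps, x$config$n_genes, x$config$n_expression_samples,
    length(x$studies),
    paste(vapply(x$studies, `[[`, character(1), "role"), collapse = ", "),
    sum(x$truth$kind == "cis"), sum(x$truth$kind == "disease")))
  invisible(x)
}
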