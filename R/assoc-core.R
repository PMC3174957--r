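# Smallest reportable p-value; anything smaller is floored and flagged so
# downstream ranking never sees an exact zero.
.P_FLOOR <- .Machine$double.xmin

assoc_stats <- function(effect = NA_real_, se = NA_real_,
                        statistic = NA_real_, p = NA_real_, df = NA_real_,
                        n_used = NA_integer_, flag = NA_character_) {
  data.frame(effect = effect, se = se, statistic = statistic, p = p,
             df = df, n_used = as.integer(n_used), flag = flag,
             stringsAsFactors = FALSE)
}

floor_p <- function(p) {
  flag <- NA_character_
  if (!is.na(p) && p < .P_FLOOR) {
    p <- .P_FLOOR
    flag <- "underflow"
  }
  list(p = p, flag = flag)
}

#' Minor allele frequency of a dosage vector
#'
#' @param dosages Numeric vector of additive allele counts in `{0, 1, 2}`,
#'   `NA` for missing.
#' @return MAF in `[0, 0.5]`: `min(f, 1 - f)` with
#'   `f = sum(dosages) / (2 * n_nonmissing)`.
#' @export
#' @examples
#' compute_maf(c(0, 0, 1, 1)) # 0.25
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) {
    stop("MAF undefined: all dosages missing", call. = FALSE)
  }
  if (any(!d %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Covariate-adjusted linear association (general linear model)
#'
#' Ordinary least squares of a quantitative response (e.g. a probe set's
#' normalized expression) on an additive genotype dosage plus covariates,
#' returning the genotype coefficient with its standard error, t statistic
#' and two-sided p-value from the t distribution with
#' `n_used - n_columns` degrees of freedom. Samples missing any of the
#' response, dosage or covariates are dropped (pairwise-complete per test).
#'
#' @param y Numeric response vector.
#' @param g Numeric dosage vector (may be `NULL` for an intercept/covariate
#'   only fit, in which case the intercept row is returned).
#' @param covariates Optional numeric matrix or data frame of covariate
#'   columns (no intercept; one is always added).
#' @return A one-row data frame: `effect`, `se`, `statistic`, `p`, `df`,
#'   `n_used`, `flag`. Rank-deficient designs (e.g. a zero-variance
#'   genotype) return `flag = "degenerate"` with missing `p`.
#' @export
ols_assoc <- function(y, g = NULL, covariates = NULL) {
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n <- length(y)
  if (!is.null(g) && length(g) != n) stop("length(g) != length(y)", call. = FALSE)
  if (!is.null(C) && nrow(C) != n) stop("nrow(covariates) != length(y)", call. = FALSE)
  keep <- !is.na(y)
  if (!is.null(g)) keep <- keep & !is.na(g)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  X <- cbind(`(Intercept)` = rep(1, sum(keep)),
             if (!is.null(g)) cbind(g = g[keep]),
             if (!is.null(C)) C[keep, , drop = FALSE])
  yk <- y[keep]
  n_used <- length(yk)
  coef_idx <- if (is.null(g)) 1L else 2L
  if (n_used < ncol(X) + 1L) {
    return(assoc_stats(n_used = n_used, flag = "degenerate"))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    return(assoc_stats(n_used = n_used, flag = "degenerate"))
  }
  beta <- qr.coef(qx, yk)
  res <- yk - X %*% beta
  df <- n_used - ncol(X)
  rss <- sum(res^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtX_inv[coef_idx, coef_idx])
  eff <- unname(beta[coef_idx])
  if (!is.finite(se) || rss <= 1e-20 * max(sum(yk^2), 1)) {
    # exact fit: residual variance is zero, Wald inference undefined
    return(assoc_stats(effect = eff, se = 0, statistic = NA_real_,
                       p = NA_real_, df = df, n_used = n_used,
                       flag = "zero_residual"))
  }
  tstat <- eff / se
  fp <- floor_p(2 * stats::pt(-abs(tstat), df = df))
  assoc_stats(effect = eff, se = se, statistic = tstat, p = fp$p, df = df,
              n_used = n_used, flag = fp$flag)
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of a binary phenotype on an
#' additive dosage plus covariates, fitted by iteratively reweighted least
#' squares (convergence tolerance 1e-8, at most 50 iterations). Returns the
#' per-allele log-odds with its Wald standard error, z statistic and
#' two-sided normal p-value; the odds ratio is `exp(effect)`.
#' Non-convergence or an implausibly large coefficient (`|effect| > 15`,
#' the signature of complete separation) yields `flag = "separation"` with
#' missing `p`.
#'
#' @inheritParams ols_assoc
#' @param y Binary 0/1 phenotype vector.
#' @return A one-row data frame as in [ols_assoc()] (with `df = NA`;
#'   inference is asymptotic normal).
#' @export
logistic_assoc <- function(y, g = NULL, covariates = NULL) {
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n <- length(y)
  keep <- !is.na(y)
  if (!is.null(g)) keep <- keep & !is.na(g)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  yk <- y[keep]
  n_used <- length(yk)
  if (!all(yk %in% c(0, 1))) stop("phenotype must be binary 0/1", call. = FALSE)
  X <- cbind(`(Intercept)` = rep(1, n_used),
             if (!is.null(g)) cbind(g = g[keep]),
             if (!is.null(C)) C[keep, , drop = FALSE])
  coef_idx <- if (is.null(g)) 1L else 2L
  if (length(unique(yk)) < 2L || n_used < ncol(X) + 1L) {
    return(assoc_stats(n_used = n_used, flag = "degenerate"))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      X, yk, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(X)) {
    return(assoc_stats(n_used = n_used, flag = "degenerate"))
  }
  eff <- unname(fit$coefficients[coef_idx])
  # Wald covariance from the information matrix evaluated AT the converged
  # coefficients (glm's stored QR carries weights one IRLS step stale)
  mu <- fit$fitted.values
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  covmat <- tryCatch(chol2inv(chol(crossprod(X * sqrt(w)))),
                     error = function(e) NULL)
  if (is.null(covmat)) {
    return(assoc_stats(effect = eff, n_used = n_used, flag = "degenerate"))
  }
  se <- sqrt(covmat[coef_idx, coef_idx])
  if (!fit$converged || !is.finite(eff) || abs(eff) > 15) {
    return(assoc_stats(effect = eff, se = se, n_used = n_used,
                       flag = "separation"))
  }
  z <- eff / se
  fp <- floor_p(2 * stats::pnorm(-abs(z)))
  assoc_stats(effect = eff, se = se, statistic = z, p = fp$p, df = NA_real_,
              n_used = n_used, flag = fp$flag)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values returned in the input order; every adjusted
#' value is at least its raw value and at most 1.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Numeric vector of BH-adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1] with no missing values", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 3309) # ~1.5e-5
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("`m` must be a positive test count", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  alpha / m
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines per-study effect estimates with weights `1 / se^2`:
#' the pooled effect is the weighted mean, its standard error
#' `1 / sqrt(sum(w))`, and `z = effect / se` is referred to the standard
#' normal. Studies with missing effect or SE are dropped.
#'
#' @param effects Numeric vector of per-study effects (e.g. log-odds).
#' @param ses Matching vector of standard errors (> 0).
#' @return One-row data frame: `effect`, `se`, `statistic` (z), `p`,
#'   `n_studies`, `flag`.
#' @export
fixed_effects_meta <- function(effects, ses) {
  stopifnot(length(effects) == length(ses))
  ok <- is.finite(effects) & is.finite(ses) & ses > 0
  if (!any(ok)) {
    return(data.frame(effect = NA_real_, se = NA_real_, statistic = NA_real_,
                      p = NA_real_, n_studies = 0L,
                      flag = "degenerate", stringsAsFactors = FALSE))
  }
  w <- 1 / ses[ok]^2
  eff <- sum(w * effects[ok]) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- eff / se
  fp <- floor_p(2 * stats::pnorm(-abs(z)))
  data.frame(effect = eff, se = se, statistic = z, p = fp$p,
             n_studies = sum(ok), flag = fp$flag, stringsAsFactors = FALSE)
}

#' Weighted-Z (Stouffer) meta-analysis
#'
#' Alternative combination rule: per-study z-scores `effect / se` are
#' combined with inverse-variance weights,
#' `z = sum(w_i z_i) / sqrt(sum(w_i^2))` with `w_i = 1 / se_i^2`. Reported
#' `effect`/`se` are the IVW pooled values (the z and p differ from
#' [fixed_effects_meta()] only when study SEs differ).
#'
#' @inheritParams fixed_effects_meta
#' @return One-row data frame as in [fixed_effects_meta()].
#' @export
stouffer_meta <- function(effects, ses) {
  stopifnot(length(effects) == length(ses))
  ok <- is.finite(effects) & is.finite(ses) & ses > 0
  if (!any(ok)) {
    return(data.frame(effect = NA_real_, se = NA_real_, statistic = NA_real_,
                      p = NA_real_, n_studies = 0L,
                      flag = "degenerate", stringsAsFactors = FALSE))
  }
  w <- 1 / ses[ok]^2
  zi <- effects[ok] / ses[ok]
  z <- sum(w * zi) / sqrt(sum(w^2))
  eff <- sum(w * effects[ok]) / sum(w)
  se <- 1 / sqrt(sum(w))
  fp <- floor_p(2 * stats::pnorm(-abs(z)))
  data.frame(effect = eff, se = se, statistic = z, p = fp$p,
             n_studies = sum(ok), flag = fp$flag, stringsAsFactors = FALSE)
}

#' Composite linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between two dosage vectors
#' (genotype/composite LD; haplotype phase is not required). Symmetric and
#' invariant to allele relabelling (`g` vs `2 - g`).
#'
#' @param g1,g2 Dosage vectors of equal length; `NA` allowed (pairwise
#'   complete).
#' @return r^2 in `[0, 1]`, or `NA` with a warning if either SNP is
#'   monomorphic among the pairwise-complete samples or fewer than 3 such
#'   samples remain.
#' @export
ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3L) {
    warning("fewer than 3 pairwise-complete samples; LD undefined")
    return(NA_real_)
  }
  a <- g1[ok]; b <- g2[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("monomorphic SNP; LD undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Genotype ancestry principal components
#'
#' Mean-imputes missing dosages per SNP, centers each SNP and scales it by
#' `sqrt(2 p (1 - p))` (the expected binomial allele-count SD), then takes
#' the top `k` left singular vectors scaled by their singular values.
#' Monomorphic SNPs are dropped. Each returned score column has mean zero;
#' signs are arbitrary.
#'
#' @param G A `genotype_matrix` (see [simulate_genotypes()]) or a plain
#'   samples-by-SNPs dosage matrix.
#' @param k Number of components.
#' @return Numeric matrix of `n_samples` rows and up to `k` columns named
#'   `PC1..PCk`. If the rank supports fewer than `k` components a warning
#'   is issued and the available ones are returned.
#' @export
genotype_pcs <- function(G, k) {
  M <- dosage_matrix(G)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  n <- nrow(M)
  # per-SNP mean imputation, then drop monomorphic columns
  p_hat <- colMeans(M, na.rm = TRUE) / 2
  for (j in seq_len(ncol(M))) {
    miss <- is.na(M[, j])
    if (any(miss)) M[miss, j] <- 2 * p_hat[j]
  }
  poly <- apply(M, 2, stats::var) > 0
  if (!any(poly)) stop("no polymorphic SNPs; PCs undefined", call. = FALSE)
  M <- M[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  Z <- sweep(M, 2, 2 * p_hat, "-")
  Z <- sweep(Z, 2, sqrt(pmax(2 * p_hat * (1 - p_hat), .Machine$double.eps)), "/")
  sv <- svd(Z, nu = min(k, n - 1L, ncol(Z)), nv = 0)
  avail <- sum(sv$d > sv$d[1] * 1e-12)
  k_eff <- min(k, ncol(sv$u), avail)
  if (k_eff < k) {
    warning(sprintf("rank supports only %d of %d requested components",
                    k_eff, k))
  }
  scores <- sv$u[, seq_len(k_eff), drop = FALSE] %*%
    diag(sv$d[seq_len(k_eff)], k_eff, k_eff)
  colnames(scores) <- paste0("PC", seq_len(k_eff))
  rownames(scores) <- rownames(M)
  scores
}

#' Quantile normalization of an expression matrix
#'
#' Forces every sample to share the same empirical distribution: each
#' sample's values are replaced by the across-sample mean order statistics
#' at that sample's ranks, ties receiving the mean of their target values.
#'
#' @param E Samples-by-probes numeric matrix with no missing values.
#' @return Matrix of the same shape; after normalization all samples have
#'   identical sorted value multisets. A single-sample matrix is returned
#'   unchanged.
#' @export
quantile_normalize <- function(E) {
  E <- as.matrix(E)
  if (anyNA(E)) stop("missing values not supported", call. = FALSE)
  if (nrow(E) <= 1L) return(E)
  # limma normalizes columns (arrays); our samples are rows
  out <- t(limma::normalizeQuantiles(t(E), ties = TRUE))
  dimnames(out) <- dimnames(E)
  out
}
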