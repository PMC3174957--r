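# Independent brute-force oracles used to cross-check the package's
# statistical primitives. These deliberately avoid the implementation's
# code paths (QR/lm machinery, p.adjust, IRLS): normal equations solved
# directly, exhaustive step-up minima, closed-form 2x2 tables, full
# eigendecompositions.

# OLS via the normal equations; returns the coefficient of column `idx`
# of the design [1, g, C], its SE, t and two-sided p.
oracle_ols <- function(y, g, C = NULL, idx = 2L) {
  X <- cbind(1, g, C)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  V <- s2 * solve(XtX)
  se <- sqrt(V[idx, idx])
  tt <- b[idx] / se
  list(effect = b[idx], se = se, statistic = tt,
       p = 2 * stats::pt(-abs(tt), df), df = df)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Closed-form log odds ratio and SE from a 2x2 exposure table.
oracle_log_or <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
  list(effect = log((case_exp * ctrl_unexp) / (case_unexp * ctrl_exp)),
       se = sqrt(1 / case_exp + 1 / case_unexp + 1 / ctrl_exp +
                   1 / ctrl_unexp))
}

# Inverse-variance fixed-effects pooling written out longhand.
oracle_ivw <- function(effects, ses) {
  w <- 1 / ses^2
  eff <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  list(effect = eff, se = se, z = eff / se)
}

# Brute-force squared correlation.
oracle_r2 <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  num <- sum((a - ma) * (b - mb))
  (num / sqrt(sum((a - ma)^2) * sum((b - mb)^2)))^2
}

# PCA scores from the full eigendecomposition of the standardized
# genotype covariance (samples x samples), matching the genotype_pcs
# standardization: mean-impute, center at 2p, scale by sqrt(2p(1-p)).
oracle_pc_scores <- function(M, k) {
  p_hat <- colMeans(M, na.rm = TRUE) / 2
  for (j in seq_len(ncol(M))) {
    miss <- is.na(M[, j])
    if (any(miss)) M[miss, j] <- 2 * p_hat[j]
  }
  keep <- apply(M, 2, stats::var) > 0
  M <- M[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  Z <- sweep(M, 2, 2 * p_hat, "-")
  Z <- sweep(Z, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  eig <- eigen(Z %*% t(Z), symmetric = TRUE)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k, k)
  scores
}

# Column-wise comparison tolerant to the arbitrary sign of each component.
expect_equal_up_to_sign <- function(A, B, tolerance = 1e-8) {
  for (j in seq_len(ncol(A))) {
    d <- min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
    expect_lt(d, tolerance)
  }
}
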