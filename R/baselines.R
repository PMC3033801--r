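# Comparison statistics: Cochran-Armitage trend test, most-significant SNP
# (MSS), rank truncated product (RTP_k), Fisher combination, and the
# admixture-maximum-likelihood (AML) EM, each with permutation significance
# in the same shared-ensemble framework as the FPC tests.

#' Cochran-Armitage trend test for one SNP
#'
#' Standard trend chi-square with dosage scores (0, 1, 2) via
#' [stats::prop.trend.test()]; `z` is the signed square root of the
#' chi-square, positive when the minor allele is enriched in cases.
#'
#' @param dosage 0/1/2 dosage vector.
#' @param y binary phenotype.
#' @return list with `z`, `chi2` and two-sided `p` (chi-square, 1 df).
#' @export
trend_test <- function(dosage, y) {
  y <- check_binary_phenotype(y)
  lev <- sort(unique(dosage))
  if (length(lev) < 2L) {
    warning("constant dosage: trend test undefined, returning p = 1")
    return(list(z = 0, chi2 = 0, p = 1))
  }
  cases <- vapply(lev, function(g) sum(y[dosage == g]), numeric(1L))
  tot <- vapply(lev, function(g) sum(dosage == g), numeric(1L))
  tt <- suppressWarnings(stats::prop.trend.test(cases, tot, score = lev))
  chi2 <- unname(tt$statistic)
  z <- sign(stats::cov(dosage, y)) * sqrt(chi2)
  list(z = z, chi2 = chi2, p = unname(tt$p.value))
}

# Vectorized trend statistics for every SNP (columns of X) against one or
# many phenotype vectors. Uses the identity chi2 = n * r^2 between the trend
# chi-square and the squared dosage-phenotype Pearson correlation (the 1/n
# vs 1/(n-1) normalizations cancel in r). Y may be an n-vector or an n x B
# matrix of permuted phenotypes; constant SNPs get chi2 = 0, p = 1.
snp_trend_stats <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  ssx <- colSums(Xc^2)
  ssy <- colSums(Yc^2)
  num <- crossprod(Xc, Yc)                      # P x B
  den <- sqrt(outer(ssx, ssy))
  r <- ifelse(den > 0, num / den, 0)
  chi2 <- n * r^2
  list(z = sign(r) * sqrt(chi2), chi2 = chi2,
       p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Most-significant-SNP statistic
#'
#' @param pvals vector of single-SNP p-values over the pathway.
#' @return the smallest p-value.
#' @export
mss_stat <- function(pvals) {
  stopifnot(length(pvals) >= 1L)
  min(pvals)
}

#' Rank-truncated-product statistic
#'
#' Product of the `k` smallest p-values (`k` clipped to the number of SNPs),
#' computed in log space.
#'
#' @param pvals vector of single-SNP p-values.
#' @param k truncation rank (typical choices 5 and 10).
#' @return the product of the k smallest p-values.
#' @export
rtp_stat <- function(pvals, k) {
  stopifnot(k >= 1L, length(pvals) >= 1L)
  exp(rtp_log_stat(pvals, k))
}

rtp_log_stat <- function(pvals, k) {
  k <- min(as.integer(k), length(pvals))
  sum(log(sort(pvals, partial = k)[seq_len(k)]))
}

#' Fisher combination statistic
#'
#' `-2 * sum(log p_i)`. Under independent uniform p-values the statistic is
#' chi-square with `2q` degrees of freedom ([fisher_pvalue_chisq()]); for
#' correlated SNP tests use the permutation p-value of
#' [baseline_pathway_test()] instead.
#'
#' @param pvals vector of p-values in (0, 1].
#' @return the Fisher combination statistic.
#' @export
fisher_stat <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  -2 * sum(log(pvals))
}

#' @rdname fisher_stat
#' @param stat a [fisher_stat()] value.
#' @param q number of combined p-values.
#' @export
fisher_pvalue_chisq <- function(stat, q)
  stats::pchisq(stat, 2L * q, lower.tail = FALSE)

# -- AML: admixture maximum likelihood -------------------------------------

# log of the mixture/null density ratio, summed over SNPs:
# lambda(alpha, zeta) = sum_j log[(1-alpha) +
#                        alpha * (exp(z*zeta) + exp(-z*zeta)) * exp(-zeta^2/2) / 2]
# i.e. the log-LR of (1-alpha) N(0,1) + alpha * 0.5 [N(zeta,1) + N(-zeta,1)]
# against N(0,1).
aml_loglr <- function(z, alpha, zeta) {
  a <- z * zeta - zeta^2 / 2
  b <- -z * zeta - zeta^2 / 2
  m <- pmax(a, b, 0)
  sum(log((1 - alpha) * exp(-m) +
            (alpha / 2) * (exp(a - m) + exp(b - m))) + m)
}

# Batched EM over columns of Z (P x B), one (alpha, zeta) pair per column.
# The per-column iteration (with a monotonicity check on the objective at
# every iterate) runs in compiled code; see src/aml_em.cpp.
aml_em_batch <- function(Z, alpha, zeta, max_iter = 500L, tol = 1e-4) {
  stopifnot(length(alpha) == ncol(Z), length(zeta) == ncol(Z))
  aml_em_cpp(Z, as.numeric(alpha), as.numeric(zeta),
             as.integer(max_iter), tol)
}

AML_STARTS <- expand.grid(alpha = c(0.01, 0.1, 0.3), zeta = c(0.5, 1, 2))

#' Admixture-maximum-likelihood fit of SNP z-statistics
#'
#' Models the signed trend statistics `z_j` as a contamination mixture: a
#' proportion `alpha` of SNPs is associated with average shifted effect
#' `+/- zeta` (two-sided, equal weights) and the rest is standard normal. The
#' EM algorithm maximizes the log-likelihood-ratio `lambda(alpha, zeta)`
#' against the pure-null model from a 3 x 3 multi-start grid
#' (`alpha in {0.01, 0.1, 0.3}`, `zeta in {0.5, 1, 2}`); the null itself
#' (`lambda = 0` at `alpha = 0`) is always included, so the maximized
#' statistic is nonnegative.
#'
#' @param z vector of signed per-SNP trend statistics.
#' @param max_iter maximum EM iterations per start.
#' @param tol absolute convergence tolerance on `lambda` (default 1e-4; the
#'   statistic enters only permutation comparisons, far coarser than this).
#' @return object of class `aml_fit`: `alpha_hat`, `zeta_hat`,
#'   `lambda_stat`, `n_iter`, `converged`.
#' @export
aml_fit <- function(z, max_iter = 500L, tol = 1e-4) {
  stopifnot(length(z) >= 1L)
  ns <- nrow(AML_STARTS)
  Z <- matrix(z, length(z), ns)
  em <- aml_em_batch(Z, AML_STARTS$alpha, AML_STARTS$zeta,
                     max_iter = max_iter, tol = tol)
  best <- which.max(em$lambda)
  if (em$lambda[best] <= 0)
    return(structure(list(alpha_hat = 0, zeta_hat = 0, lambda_stat = 0,
                          n_iter = max(em$iters), converged = TRUE),
                     class = "aml_fit"))
  structure(list(alpha_hat = em$alpha[best], zeta_hat = em$zeta[best],
                 lambda_stat = em$lambda[best], n_iter = em$iters[best],
                 converged = em$converged[best]),
            class = "aml_fit")
}

#' @export
print.aml_fit <- function(x, ...) {
  cat(sprintf("AML fit: alpha = %.3f, zeta = %.3f, lambda = %.3f (%d iter%s)\n",
              x$alpha_hat, x$zeta_hat, x$lambda_stat, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

# Maximized AML statistic for each column of a P x B z-matrix (multi-start,
# batched across columns and starts), floored at 0.
aml_stat_batch <- function(Zmat, max_iter = 500L, tol = 1e-4) {
  B <- ncol(Zmat)
  ns <- nrow(AML_STARTS)
  Zrep <- Zmat[, rep(seq_len(B), each = ns), drop = FALSE]
  em <- aml_em_batch(Zrep, rep(AML_STARTS$alpha, B), rep(AML_STARTS$zeta, B),
                     max_iter = max_iter, tol = tol)
  lam <- matrix(em$lambda, ns, B)
  pmax(apply(lam, 2L, max), 0)
}

#' Pathway test with a comparison statistic
#'
#' Computes single-SNP trend p-values (and z statistics) for the pathway's
#' SNPs, forms the chosen summary statistic, and assesses significance by the
#' same phenotype-permutation ensemble used by the FPC tests, so method
#' comparisons pair replicates correctly. Smaller is more extreme for MSS and
#' RTP; larger for Fisher and AML. The p-value convention matches
#' [fpc_pathway_test()] (`"literal"` strict exceedance by default).
#'
#' @param X `n x P` dosage matrix of the pathway's SNPs.
#' @param y binary phenotype.
#' @param method one of `"mss"`, `"rtp"`, `"fisher"`, `"aml"`.
#' @param k truncation rank for RTP (default 5).
#' @param B number of permutations when `perms` is NULL.
#' @param perms optional shared `n x B` permutation matrix.
#' @param seed seed when `perms` is NULL.
#' @param estimator `"literal"` or `"add_one"`.
#' @return list with `method`, `stat`, `p_value`, `perm_stats`, `B` (plus
#'   the [aml_fit()] under `fit` for AML).
#' @export
baseline_pathway_test <- function(X, y, method = c("mss", "rtp", "fisher", "aml"),
                                  k = 5L, B = 200L, perms = NULL, seed = NULL,
                                  estimator = c("literal", "add_one")) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  X <- as.matrix(X)
  y <- check_binary_phenotype(y)
  if (is.null(perms)) perms <- make_permutations(nrow(X), B, seed)
  Yperm <- matrix(y[perms], nrow(X), ncol(perms))
  baseline_core(snp_trend_stats(X, y), snp_trend_stats(X, Yperm),
                method, k, estimator)
}

# shared core: summary statistic + permutation p-value from precomputed
# observed/permuted trend statistics (one pathway, one method)
baseline_core <- function(obs, per, method, k = 5L,
                          estimator = c("literal", "add_one")) {
  estimator <- match.arg(estimator)
  B <- ncol(per$p)
  fit <- NULL
  if (method == "aml") {
    f <- aml_fit(drop(obs$z))
    stat <- f$lambda_stat
    fit <- f
    perm_stats <- aml_stat_batch(per$z)
  } else {
    stat_fun <- switch(method,
      mss = function(p) log(mss_stat(p)),
      rtp = function(p) rtp_log_stat(p, k),
      fisher = function(p) fisher_stat(p))
    stat <- stat_fun(drop(obs$p))
    perm_stats <- apply(per$p, 2L, stat_fun)
  }
  larger_extreme <- method %in% c("fisher", "aml")
  exceed <- if (larger_extreme) perm_stats > stat else perm_stats < stat
  exceed_eq <- if (larger_extreme) perm_stats >= stat else perm_stats <= stat
  p <- if (estimator == "literal") sum(exceed) / B
       else (1 + sum(exceed_eq)) / (B + 1)
  out_stat <- if (method %in% c("mss", "rtp")) exp(stat) else stat
  out_perm <- if (method %in% c("mss", "rtp")) exp(perm_stats) else perm_stats
  out <- list(method = if (method == "rtp") paste0("rtp", k) else method,
              stat = out_stat, p_value = p, perm_stats = out_perm, B = B)
  if (!is.null(fit)) out$fit <- fit
  out
}
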