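# Pathway-level likelihood-ratio tests with a size-constrained permutation
# null, and permutation-based FDR/FWER across pathways via normalized LR
# statistics.

#' Likelihood-ratio test of a pathway using all K genes
#'
#' LR statistic of the logistic model on all K gene scores against the
#' intercept-only model; the p-value uses the chi-square approximation with
#' K degrees of freedom.
#'
#' @param scores `n x K` gene-score matrix.
#' @param y binary phenotype (both classes present).
#' @return list with `T` (LR statistic), `df` (= K) and `p_chi2`.
#' @export
lr_full <- function(scores, y) {
  y <- check_binary_phenotype(y)
  scores <- as.matrix(scores)
  T <- logistic_lr(scores, y, warn = TRUE)
  list(T = T, df = ncol(scores), p_chi2 = stats::pchisq(T, ncol(scores),
                                                        lower.tail = FALSE))
}

#' Likelihood-ratio statistic of a gene subset
#'
#' LR of the m-gene logistic model against intercept-only. With the subset
#' equal to all K genes this reduces to [lr_full()]'s statistic.
#'
#' @param scores_subset `n x m` score matrix restricted to the subset.
#' @param y binary phenotype.
#' @return scalar LR statistic (>= 0).
#' @export
lr_subset <- function(scores_subset, y) {
  y <- check_binary_phenotype(y)
  scores_subset <- as.matrix(scores_subset)
  stopifnot(ncol(scores_subset) >= 1L)
  logistic_lr(scores_subset, y, warn = TRUE)
}

#' FPC pathway test with size-constrained permutation p-value
#'
#' Observed pipeline: [lasso_path()] -> [select_subset()] (AIC or BIC) ->
#' LR statistic of the selected m-gene subset. Each permutation shuffles the
#' phenotype, re-selects a subset constrained to the observed size m via
#' [constrained_subset()], and recomputes the LR statistic. The default
#' p-value is the literal exceedance fraction `#{T(pi) > T}/B`; the add-one
#' estimator `(1 + #{T(pi) >= T})/(B + 1)` is available via `estimator`.
#'
#' Several criteria may be requested at once; the permutation paths are then
#' shared across criteria, which is both faster and what a common-ensemble
#' FDR requires.
#'
#' @param scores `n x K` gene-score matrix (gene ids as column names).
#' @param y binary phenotype.
#' @param criterion character vector from `c("bic", "aic")`.
#' @param B number of permutations (used when `perms` is NULL).
#' @param perms optional `n x B` permutation-index matrix from
#'   [make_permutations()]; share one matrix across pathways and methods.
#' @param seed seed for the permutation ensemble when `perms` is NULL.
#' @param estimator `"literal"` or `"add_one"`.
#' @param ... passed to [lasso_path()] (grid size, standardization).
#' @return for a single criterion, an object of class `pathway_fpc_test`:
#'   `criterion`, `K`, `T`, `m`, `subset` (gene ids), `p_value`,
#'   `perm_stats` (length B), `B`, `estimator`. For several criteria, a named
#'   list of such objects.
#' @export
fpc_pathway_test <- function(scores, y, criterion = "bic", B = 200L,
                             perms = NULL, seed = NULL,
                             estimator = c("literal", "add_one"), ...) {
  estimator <- match.arg(estimator)
  criterion <- match.arg(criterion, c("bic", "aic"), several.ok = TRUE)
  scores <- as.matrix(scores)
  y <- check_binary_phenotype(y)
  n <- nrow(scores)
  K <- ncol(scores)
  if (is.null(perms)) perms <- make_permutations(n, B, seed)
  B <- ncol(perms)
  if (B < 20L) warning("B = ", B, " permutations gives a very coarse ",
                       "p-value/FDR resolution")
  path <- lasso_path(scores, y, ...)
  ll0 <- intercept_loglik(y)  # invariant under permutation of y
  sel <- lapply(criterion, function(cr) select_subset(path, cr, scores, y))
  names(sel) <- criterion
  T_obs <- vapply(sel, function(s) max(2 * (s$loglik - ll0), 0), numeric(1L))
  m_by_crit <- vapply(sel, `[[`, integer(1L), "m")
  perm_stats <- matrix(NA_real_, B, length(criterion),
                       dimnames = list(NULL, criterion))
  sdv <- apply(scores, 2L, sd_pop)
  for (b in seq_len(B)) {
    yb <- y[perms[, b]]
    lr_by_m <- perm_constrained_lr(scores, yb, m_by_crit, ll0, sdv = sdv, ...)
    perm_stats[b, ] <- lr_by_m[as.character(m_by_crit[criterion])]
  }
  out <- lapply(criterion, function(cr) {
    ps <- perm_stats[, cr]
    p <- if (estimator == "literal") sum(ps > T_obs[cr]) / B
         else (1 + sum(ps >= T_obs[cr])) / (B + 1)
    structure(list(criterion = cr, K = K, T = unname(T_obs[cr]),
                   m = unname(m_by_crit[cr]), subset = sel[[cr]]$gene_ids,
                   p_value = p, perm_stats = ps, B = B,
                   estimator = estimator),
              class = "pathway_fpc_test")
  })
  names(out) <- criterion
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
print.pathway_fpc_test <- function(x, ...) {
  cat(sprintf("FPC_%s pathway test: K = %d, m = %d, T = %.3f, p = %.4g (B = %d)\n",
              toupper(x$criterion), x$K, x$m, x$T, x$p_value, x$B))
  cat("  selected genes:", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize an LR statistic against its permutation distribution
#'
#' `NLR = (T - mean(T_perm)) / sd(T_perm)` (sample SD, denominator B - 1);
#' every permuted statistic is normalized by the same mean and SD so that
#' pathways of different size become comparable.
#'
#' @param T observed LR statistic.
#' @param perm_stats vector of permuted LR statistics (length >= 2).
#' @return list with `nlr` (scalar) and `nlr_perm` (normalized permuted
#'   statistics).
#' @export
nlr <- function(T, perm_stats) {
  if (length(perm_stats) < 2L) stop("need at least 2 permuted statistics")
  mu <- mean(perm_stats)
  sdev <- stats::sd(perm_stats)
  if (sdev == 0) stop("degenerate permutation distribution (SD = 0)")
  list(nlr = (T - mu) / sdev, nlr_perm = (perm_stats - mu) / sdev)
}

#' Permutation-based FDR and FWER across pathways
#'
#' Each pathway's statistic and permutation ensemble are first normalized by
#' [nlr()]. With `NLR(G)` the observed normalized statistic of pathway G and
#' `NLR(AG, pi)` the normalized statistic of any pathway AG in permutation
#' pi (all pathways sharing one permutation stream):
#' \describe{
#'   \item{FDR(G)}{average over permutations of `#{AG : NLR(AG, pi) >=
#'     NLR(G)}`, divided by `#{AG : NLR(AG) >= NLR(G)}`, capped at 1. The
#'     `variant = "literal"` form divides the un-averaged total exceedance
#'     count over all permutations by the observed count instead (and is then
#'     capped at 1 as well).}
#'   \item{FWER(G)}{fraction of permutations in which `max_AG NLR(AG, pi) >=
#'     NLR(G)`.}
#' }
#'
#' @param results list of `pathway_fpc_test` objects (or any lists with
#'   elements `T` and `perm_stats`), all with the same number of permutations
#'   from one shared ensemble.
#' @param variant `"averaged"` (per-permutation average numerator; default)
#'   or `"literal"` (pooled count).
#' @return `results` with `NLR`, `FDR` and `FWER` fields filled in.
#' @export
fdr_fwer <- function(results, variant = c("averaged", "literal")) {
  variant <- match.arg(variant)
  Bs <- vapply(results, function(r) length(r$perm_stats), integer(1L))
  if (length(unique(Bs)) != 1L)
    stop("all pathways must share the same number of permutations B")
  B <- Bs[1L]
  norm <- lapply(results, function(r) nlr(r$T, r$perm_stats))
  n_obs <- vapply(norm, `[[`, numeric(1L), "nlr")
  n_perm <- vapply(norm, `[[`, numeric(B), "nlr_perm")  # B x n_pathways
  if (is.null(dim(n_perm))) n_perm <- matrix(n_perm, nrow = B)
  max_perm <- apply(n_perm, 1L, max)
  for (g in seq_along(results)) {
    obs_ge <- sum(n_obs >= n_obs[g])
    perm_ge <- sum(n_perm >= n_obs[g])
    num <- if (variant == "averaged") perm_ge / B else perm_ge
    results[[g]]$NLR <- unname(n_obs[g])
    results[[g]]$FDR <- min(num / obs_ge, 1)
    results[[g]]$FWER <- mean(max_perm >= n_obs[g])
  }
  results
}

#' Test every pathway of a collection with the FPC pipeline
#'
#' Builds gene scores per pathway (restricted to genes with mapped SNPs),
#' runs [fpc_pathway_test()] for each pathway on one shared permutation
#' ensemble, applies [fdr_fwer()], and returns the results table.
#'
#' @param ds a [genotype_dataset()].
#' @param gm a [map_snps_to_genes()] gene map.
#' @param pc a [read_pathways()] collection (apply [filter_pathways()]
#'   first).
#' @param criterion `"bic"` or `"aic"`.
#' @param B number of permutations.
#' @param seed master seed for the shared permutation ensemble.
#' @param fdr_variant passed to [fdr_fwer()].
#' @param estimator passed to [fpc_pathway_test()].
#' @param verbose print per-pathway progress.
#' @param ... passed to [lasso_path()].
#' @return data.frame with columns `pathway_id`, `K`, `m`, `T`, `p_value`,
#'   `NLR`, `FDR`, `FWER`, `selected_genes` (semicolon-joined).
#' @export
test_pathways <- function(ds, gm, pc, criterion = "bic", B = 200L,
                          seed = NULL, fdr_variant = "averaged",
                          estimator = "literal", verbose = FALSE, ...) {
  criterion <- match.arg(criterion, c("bic", "aic"))
  if (length(pc) == 0L) stop("empty pathway collection")
  perms <- make_permutations(length(ds$y), B, seed)
  results <- vector("list", length(pc))
  for (i in seq_along(pc)) {
    genes <- intersect(pc[[i]]$genes, names(gm$assignments))
    if (length(genes) == 0L) stop("pathway with no mapped genes: ",
                                  names(pc)[i])
    gs <- build_gene_scores(ds, gm, genes)
    t0 <- proc.time()[["elapsed"]]
    results[[i]] <- fpc_pathway_test(gs$scores, ds$y, criterion,
                                     perms = perms, estimator = estimator,
                                     ...)
    if (verbose)
      message(sprintf("[%d/%d] %s: K=%d m=%d p=%.4g (%.1fs)", i, length(pc),
                      names(pc)[i], results[[i]]$K, results[[i]]$m,
                      results[[i]]$p_value,
                      proc.time()[["elapsed"]] - t0))
  }
  results <- fdr_fwer(results, variant = fdr_variant)
  data.frame(
    pathway_id = names(pc),
    K = vapply(results, `[[`, integer(1L), "K"),
    m = vapply(results, `[[`, integer(1L), "m"),
    T = vapply(results, `[[`, numeric(1L), "T"),
    p_value = vapply(results, `[[`, numeric(1L), "p_value"),
    NLR = vapply(results, `[[`, numeric(1L), "NLR"),
    FDR = vapply(results, `[[`, numeric(1L), "FDR"),
    FWER = vapply(results, `[[`, numeric(1L), "FWER"),
    selected_genes = vapply(results, function(r)
      paste(r$subset, collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
}
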