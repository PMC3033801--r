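# Power / type-I-error / selection-quality estimation over simulated
# replicates, with Wald confidence intervals and paired McNemar comparisons
# between methods.

#' Wald confidence interval for a proportion
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, clipped to [0, 1] and rounded
#' to 3 decimals for reporting (e.g. 0.050 at n = 500 gives (0.031, 0.069)).
#'
#' @param p_hat estimated proportion.
#' @param n number of replicates.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
wald_ci <- function(p_hat, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  round(c(max(0, p_hat - half), min(1, p_hat + half)), 3)
}

#' Rejection rate over replicates with confidence interval
#'
#' Proportion of replicate p-values at or below `alpha` (power under an
#' alternative, type I error under the null), with its Wald interval.
#'
#' @param pvals vector of per-replicate p-values.
#' @param alpha significance level (default 0.05, inclusive).
#' @param conf confidence level for the interval.
#' @return list with `rate`, `ci_low`, `ci_high`, `n`.
#' @export
rejection_rate <- function(pvals, alpha = 0.05, conf = 0.95) {
  stopifnot(length(pvals) >= 1L)
  rate <- mean(pvals <= alpha)
  ci <- wald_ci(rate, length(pvals), conf)
  list(rate = rate, ci_low = ci[1L], ci_high = ci[2L], n = length(pvals))
}

#' Positive selection rate and selection FDR against known truth
#'
#' `PSR = # truly associated genes selected / # associated genes`;
#' `FDR = # selected genes not associated / # selected genes` (0 when
#' nothing is selected).
#'
#' @param selected character vector of selected gene ids.
#' @param truth character vector of truly associated gene ids (non-empty).
#' @return list with `psr` and `fdr_sel`.
#' @export
psr_fdr <- function(selected, truth) {
  if (length(truth) == 0L) stop("truth set must be non-empty for PSR")
  tp <- length(intersect(selected, truth))
  list(psr = tp / length(truth),
       fdr_sel = if (length(selected) == 0L) 0
                 else (length(selected) - tp) / length(selected))
}

#' McNemar test for a paired difference in rejection rates
#'
#' Exact binomial McNemar on the discordant pairs when there are fewer than
#' 25 of them, otherwise the continuity-corrected chi-square version.
#'
#' @param rej_a,rej_b paired logical/0-1 rejection vectors over the same
#'   replicates.
#' @return two-sided p-value.
#' @export
mcnemar_power_test <- function(rej_a, rej_b) {
  stopifnot(length(rej_a) == length(rej_b))
  a <- as.logical(rej_a)
  b <- as.logical(rej_b)
  n10 <- sum(a & !b)
  n01 <- sum(!a & b)
  nd <- n10 + n01
  if (nd == 0L) return(1)
  if (nd < 25L) return(stats::binom.test(n10, nd, 0.5)$p.value)
  tab <- matrix(c(sum(a & b), n01, n10, sum(!a & !b)), 2L)
  stats::mcnemar.test(tab, correct = TRUE)$p.value
}

ALL_METHODS <- c("fpc_aic", "fpc_bic", "fpc_full", "aml", "mss",
                 "rtp5", "rtp10", "fisher")

#' Per-replicate p-values of every method on one simulated dataset
#'
#' Runs the requested methods on a [simulate_replicate()] result with one
#' shared permutation ensemble (so the methods are paired permutation-wise).
#' `fpc_full` uses its chi-square(K) approximation; all other methods are
#' permutation-based.
#'
#' @param sim a [simulate_replicate()] object.
#' @param B number of permutations.
#' @param methods subset of
#'   `c("fpc_aic","fpc_bic","fpc_full","aml","mss","rtp5","rtp10","fisher")`.
#' @param perm_seed seed for the shared permutation ensemble.
#' @param return_selection also return the AIC/BIC selected gene subsets.
#' @return named p-value vector; with `return_selection`, a list
#'   `(pvals, selection)` where `selection` maps criterion to gene ids.
#' @export
replicate_method_pvalues <- function(sim, B = 200L, methods = ALL_METHODS,
                                     perm_seed = NULL,
                                     return_selection = FALSE) {
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  ds <- sim$ds
  y <- ds$y
  perms <- make_permutations(length(y), B, perm_seed)
  pvals <- stats::setNames(rep(NA_real_, length(methods)), methods)
  selection <- list()
  fpc_crit <- sub("fpc_", "", intersect(c("fpc_bic", "fpc_aic"), methods))
  if (length(fpc_crit) || "fpc_full" %in% methods)
    gs <- build_gene_scores(ds, sim$gene_map)
  if (length(fpc_crit)) {
    res <- fpc_pathway_test(gs$scores, y, criterion = fpc_crit, perms = perms)
    if (inherits(res, "pathway_fpc_test"))
      res <- stats::setNames(list(res), fpc_crit)
    for (cr in fpc_crit) {
      pvals[paste0("fpc_", cr)] <- res[[cr]]$p_value
      selection[[cr]] <- res[[cr]]$subset
    }
  }
  if ("fpc_full" %in% methods)
    pvals["fpc_full"] <- lr_full(gs$scores, y)$p_chi2
  base <- intersect(c("aml", "mss", "rtp5", "rtp10", "fisher"), methods)
  if (length(base)) {
    # trend statistics are shared across all SNP-summary methods
    obs <- snp_trend_stats(ds$dosages, y)
    per <- snp_trend_stats(ds$dosages, matrix(y[perms], length(y)))
    for (m in base) {
      bt <- baseline_core(obs, per,
                          method = if (m %in% c("rtp5", "rtp10")) "rtp" else m,
                          k = if (m == "rtp10") 10L else 5L)
      pvals[m] <- bt$p_value
    }
  }
  if (return_selection) list(pvals = pvals, selection = selection)
  else pvals
}

#' Type-I-error study under the global null
#'
#' Simulates `R` independent null replicates of a pathway pattern (genotypes
#' independent of the phenotype, LD-free by default) and computes every
#' method's p-value with `B` phenotype permutations per replicate, all
#' randomness flowing from one master seed.
#'
#' @param R number of replicates.
#' @param B permutations per replicate.
#' @param n_cases,n_controls per-replicate sample sizes.
#' @param pattern pattern name or a [sim_pattern()] object.
#' @param ld LD model for the null genotypes (default independent).
#' @param methods methods to evaluate (see [replicate_method_pvalues()]).
#' @param alpha nominal level.
#' @param seed master seed.
#' @param verbose print progress every 50 replicates.
#' @return list with `pvals` (`R x methods` matrix), `rates` (data.frame
#'   `method`, `rate`, `ci_low`, `ci_high`), `R`, `B`, `alpha`.
#' @export
type_one_error_study <- function(R = 500L, B = 200L, n_cases = 300L,
                                 n_controls = 300L, pattern = "pattern1",
                                 ld = list(model = "independent"),
                                 methods = ALL_METHODS, alpha = 0.05,
                                 seed = NULL, verbose = FALSE) {
  pat <- if (inherits(pattern, "sim_pattern")) pattern
         else sim_pattern(pattern, n_cases, n_controls)
  seeds <- draw_seeds(2L * R, seed)
  pvals <- matrix(NA_real_, R, length(methods),
                  dimnames = list(NULL, methods))
  for (r in seq_len(R)) {
    sim <- simulate_replicate(pat, n_cases = n_cases, n_controls = n_controls,
                              ld = ld, null = TRUE, seed = seeds[r])
    pvals[r, ] <- replicate_method_pvalues(sim, B, methods,
                                           perm_seed = seeds[R + r])
    if (verbose && r %% 50L == 0L)
      message("null replicate ", r, "/", R)
  }
  rates <- do.call(rbind, lapply(methods, function(m) {
    rr <- rejection_rate(pvals[, m], alpha)
    data.frame(method = m, rate = rr$rate, ci_low = rr$ci_low,
               ci_high = rr$ci_high, stringsAsFactors = FALSE)
  }))
  list(pvals = pvals, rates = rates, R = R, B = B, alpha = alpha)
}

#' Power and gene-selection study under a pattern alternative
#'
#' Simulates `R` replicates of a pattern with attenuation factor `f`,
#' computes every method's p-value, and scores the AIC/BIC-selected gene
#' subsets against the simulation truth (positive selection rate and
#' selection FDR).
#'
#' @inheritParams type_one_error_study
#' @param f attenuation factor applied to the pattern's relative risks.
#' @param ld LD model (default the pattern's block model).
#' @return list with `pvals`, `rates`, `selection` (data.frame `replicate`,
#'   `criterion`, `m`, `psr`, `fdr_sel`), `R`, `B`, `alpha`, `f`.
#' @export
power_study <- function(pattern = "pattern1", f = 1, R = 200L, B = 200L,
                        n_cases = 1350L, n_controls = 1350L, ld = NULL,
                        methods = ALL_METHODS, alpha = 0.05, seed = NULL,
                        verbose = FALSE) {
  pat <- if (inherits(pattern, "sim_pattern")) pattern
         else sim_pattern(pattern, n_cases, n_controls)
  ld <- ld %||% pat$ld
  seeds <- draw_seeds(2L * R, seed)
  pvals <- matrix(NA_real_, R, length(methods),
                  dimnames = list(NULL, methods))
  sel_rows <- list()
  for (r in seq_len(R)) {
    sim <- simulate_replicate(pat, f = f, n_cases = n_cases,
                              n_controls = n_controls, ld = ld,
                              seed = seeds[r])
    res <- replicate_method_pvalues(sim, B, methods, perm_seed = seeds[R + r],
                                    return_selection = TRUE)
    pvals[r, ] <- res$pvals
    for (cr in names(res$selection)) {
      q <- psr_fdr(res$selection[[cr]], sim$truth$assoc_genes)
      sel_rows[[length(sel_rows) + 1L]] <-
        data.frame(replicate = r, criterion = cr,
                   m = length(res$selection[[cr]]), psr = q$psr,
                   fdr_sel = q$fdr_sel, stringsAsFactors = FALSE)
    }
    if (verbose && r %% 25L == 0L)
      message("power replicate ", r, "/", R)
  }
  rates <- do.call(rbind, lapply(methods, function(m) {
    rr <- rejection_rate(pvals[, m], alpha)
    data.frame(method = m, rate = rr$rate, ci_low = rr$ci_low,
               ci_high = rr$ci_high, stringsAsFactors = FALSE)
  }))
  list(pvals = pvals, rates = rates,
       selection = do.call(rbind, sel_rows), R = R, B = B, alpha = alpha,
       f = f)
}
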