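# LASSO-path gene-subset selection on FPC scores.
#
# The penalized logistic log-likelihood is logL(beta) - n*lambda*sum(|beta_j|)
# with the intercept never penalized. glmnet minimizes the equivalent
# objective -(1/n)logL + lambda*||beta||_1, so its lambda coincides with ours.
# Candidate subsets are the distinct active sets met as lambda increases from
# 0 (all K genes) towards lambda_max (empty set); AIC/BIC are evaluated on
# unpenalized maximum-likelihood REFITS of each candidate.

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))  # 1/n scaling, as in glmnet

#' LASSO regularization path over gene scores
#'
#' Solves the L1-penalized logistic regression of the phenotype on the K
#' gene scores over a fine lambda grid: 100 log-spaced values from
#' `lambda_max` (the smallest lambda with an empty active set, computed from
#' the score/residual inner products) down to `lambda_max * 1e-4`, plus
#' lambda = 0. Each distinct non-empty active set is recorded in order of
#' increasing lambda; the first subset (lambda = 0) contains all K genes.
#' Scores are standardized to unit variance inside the solver by default
#' (penalty fairness across genes) with coefficients reported on the original
#' scale.
#'
#' @param scores numeric `n x K` gene-score matrix with gene ids as column
#'   names.
#' @param y binary 0/1 phenotype; both classes must be present.
#' @param nlambda number of log-spaced grid points (default 100).
#' @param lambda_min_ratio smallest grid lambda as a fraction of lambda_max.
#' @param standardize standardize scores inside the solver (default TRUE).
#' @param thresh coordinate-descent convergence threshold (default 1e-6;
#'   active sets are stable well above this).
#' @return object of class `subset_path`: `gene_ids`; `lambda_grid`
#'   (increasing, starting at 0); `beta0_grid`, `beta_grid` (intercepts and
#'   K x L coefficients along the grid, original scale); `sd` (per-gene
#'   solver-scale standard deviations); `lambdas` and `subsets` (the lambda of
#'   first appearance and gene-index content of each distinct active set,
#'   increasing lambda, empties dropped).
#' @export
lasso_path <- function(scores, y, nlambda = 100L, lambda_min_ratio = 1e-4,
                       standardize = TRUE, thresh = 1e-6) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  K <- ncol(scores)
  y <- check_binary_phenotype(y)
  gene_ids <- colnames(scores) %||% paste0("g", seq_len(K))
  sdv <- apply(scores, 2L, sd_pop)
  if (K == 1L) {
    fit <- fit_logistic(scores, y, warn = FALSE)
    out <- list(gene_ids = gene_ids, lambda_grid = 0,
                beta0_grid = fit$coef[1L],
                beta_grid = matrix(fit$coef[2L], 1L, 1L,
                                   dimnames = list(gene_ids, NULL)),
                sd = sdv, lambdas = 0, subsets = list(1L),
                standardize = standardize, n = n)
    return(structure(out, class = "subset_path"))
  }
  r0 <- y - mean(y)
  scale_j <- if (standardize) ifelse(sdv > 0, sdv, Inf) else rep(1, K)
  lmax <- max(abs(drop(crossprod(scores, r0)) / scale_j)) / n
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  grid_dec <- c(exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                        length.out = nlambda)), 0)
  fit <- tryCatch(
    glmnet::glmnet(scores, y, family = "binomial", lambda = grid_dec,
                   standardize = standardize, thresh = thresh,
                   maxit = 10^6),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$lambda) < length(grid_dec)) {
    # degenerate unpenalized end (e.g. perfect separation): keep the
    # penalized part of the grid and close it with a ridge-stabilized fit
    warning("penalized path unstable at lambda = 0; ",
            "using ridge-stabilized fit (penalty 1e-8) for the full model")
    fitp <- glmnet::glmnet(scores, y, family = "binomial",
                           lambda = grid_dec[-length(grid_dec)],
                           standardize = standardize, thresh = thresh,
                           maxit = 10^6)
    beta_dec <- as.matrix(fitp$beta)
    a0_dec <- fitp$a0
    bridge <- ridge_logistic(scores, y)
    beta_dec <- cbind(beta_dec, bridge[-1L])
    a0_dec <- c(a0_dec, bridge[1L])
  } else {
    beta_dec <- as.matrix(fit$beta)
    a0_dec <- fit$a0
  }
  ord <- rev(seq_len(ncol(beta_dec)))  # increasing lambda
  lambda_grid <- grid_dec[ord]
  beta_grid <- beta_dec[, ord, drop = FALSE]
  beta0_grid <- unname(a0_dec[ord])
  rownames(beta_grid) <- gene_ids
  active <- lapply(seq_along(lambda_grid), function(l) {
    if (lambda_grid[l] == 0) seq_len(K) else which(beta_grid[, l] != 0)
  })
  lambdas <- numeric(0)
  subsets <- list()
  prev <- NULL
  for (l in seq_along(active)) {
    a <- active[[l]]
    if (length(a) == 0L) next
    if (!is.null(prev) && identical(a, prev)) next
    subsets[[length(subsets) + 1L]] <- a
    lambdas <- c(lambdas, lambda_grid[l])
    prev <- a
  }
  structure(list(gene_ids = gene_ids, lambda_grid = lambda_grid,
                 beta0_grid = beta0_grid, beta_grid = beta_grid, sd = sdv,
                 lambdas = lambdas, subsets = subsets,
                 standardize = standardize, n = n),
            class = "subset_path")
}

#' @export
print.subset_path <- function(x, ...) {
  cat(sprintf("subset_path: %d genes, %d distinct candidate subsets (sizes %s)\n",
              length(x$gene_ids), length(x$subsets),
              paste(vapply(x$subsets, length, integer(1L)), collapse = ",")))
  invisible(x)
}

#' Dump a subset path as a data.frame
#'
#' One row per distinct candidate subset: lambda of first appearance, size,
#' and semicolon-joined gene ids. Convenient for TSV export when debugging.
#'
#' @param path a [lasso_path()] object.
#' @return data.frame with columns `lambda`, `size`, `genes`.
#' @export
path_table <- function(path) {
  data.frame(
    lambda = path$lambdas,
    size = vapply(path$subsets, length, integer(1L)),
    genes = vapply(path$subsets, function(s)
      paste(path$gene_ids[s], collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
}

ic_score <- function(genes, scores, y, penalty_per_gene) {
  stopifnot(length(genes) >= 1L)
  idx <- if (is.character(genes)) match(genes, colnames(scores)) else genes
  if (anyNA(idx)) stop("unknown gene in subset: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  fit <- fit_logistic(scores[, idx, drop = FALSE], y, warn = FALSE)
  if (!fit$converged)
    stop("refit did not converge for subset: ",
         paste(colnames(scores)[idx], collapse = ", "))
  list(score = -2 * fit$loglik + penalty_per_gene * length(idx),
       loglik = fit$loglik)
}

#' AIC of a candidate gene subset
#'
#' `-2 logL + 2 v(S)` where `logL` is the maximized unpenalized logistic
#' log-likelihood of the genes in `S` (refit, not the penalized solution) and
#' `v(S)` counts genes (the intercept is not counted).
#'
#' @param genes gene ids (or column indices) of the subset.
#' @param scores gene-score matrix.
#' @param y binary phenotype.
#' @return scalar AIC.
#' @export
aic_score <- function(genes, scores, y)
  ic_score(genes, scores, y, 2)$score

#' BIC of a candidate gene subset
#'
#' `-2 logL + log(n) v(S)`; see [aic_score()].
#'
#' @inheritParams aic_score
#' @return scalar BIC.
#' @export
bic_score <- function(genes, scores, y)
  ic_score(genes, scores, y, log(length(y)))$score

#' Select the best subset on a LASSO path by AIC or BIC
#'
#' Evaluates the information criterion on an unpenalized refit of every
#' distinct candidate subset recorded on the path and returns the minimizer;
#' ties are broken by smaller subset size, then by earlier position on the
#' path.
#'
#' @param path a [lasso_path()] object.
#' @param criterion `"aic"` or `"bic"`.
#' @param scores,y the data the path was fit on.
#' @return object of class `selected_subset`: `gene_ids`, `idx` (column
#'   indices), `m` (subset size), `criterion`, `score` (criterion value) and
#'   `loglik` (refit maximized log-likelihood).
#' @export
select_subset <- function(path, criterion = c("bic", "aic"), scores, y) {
  criterion <- match.arg(criterion)
  pen <- if (criterion == "aic") 2 else log(path$n)
  cand <- lapply(path$subsets, ic_score, scores = scores, y = y,
                 penalty_per_gene = pen)
  sc <- vapply(cand, `[[`, numeric(1L), "score")
  sizes <- vapply(path$subsets, length, integer(1L))
  best <- order(sc, sizes, seq_along(sc))[1L]
  structure(list(gene_ids = path$gene_ids[path$subsets[[best]]],
                 idx = path$subsets[[best]],
                 m = sizes[best], criterion = criterion,
                 score = sc[best], loglik = cand[[best]]$loglik),
            class = "selected_subset")
}

#' @export
print.selected_subset <- function(x, ...) {
  cat(sprintf("selected_subset (%s = %.3f): %d gene(s): %s\n",
              toupper(x$criterion), x$score, x$m,
              paste(x$gene_ids, collapse = ", ")))
  invisible(x)
}

#' Size-constrained subset for a permuted phenotype
#'
#' Re-runs the LASSO path on `(scores, y_perm)` and extracts a subset of
#' exactly `m` genes. Two rules are available:
#' \describe{
#'   \item{`"criterion"` (default)}{the same selection as the observed
#'     pipeline restricted to size m: among the path's distinct candidate
#'     subsets with exactly m genes, take the one whose unpenalized refit
#'     maximizes the likelihood (the information-criterion minimizer at
#'     fixed size). When no grid lambda yields exactly m active genes, fall
#'     back to the `"truncate"` rule. Re-applying the observed selection map
#'     keeps observed and permuted statistics exchangeable under the null —
#'     the weaker truncation rule produces stochastically smaller permuted
#'     statistics and an inflated type I error for liberal criteria.}
#'   \item{`"truncate"`}{at the largest grid lambda whose active set has
#'     size at least m, keep the m genes with largest absolute coefficient
#'     (on the solver's standardized scale when the path is standardized;
#'     ties by gene order). The lambda = 0 active set always has size
#'     K >= m.}
#' }
#' Constraining the permutation subsets to the observed size keeps the
#' permuted statistics on the same nominal chi-square(m) scale as the
#' observed one. How to re-select when no lambda yields exactly `m` active
#' genes is not uniquely determined; both readings are documented choices.
#'
#' @param scores gene-score matrix.
#' @param y_perm permuted binary phenotype.
#' @param m required subset size, `1 <= m <= K`.
#' @param path optional precomputed [lasso_path()] for `(scores, y_perm)`;
#'   supplied by callers that reuse one path for several sizes.
#' @param rule `"criterion"` or `"truncate"` (see above).
#' @param ... passed to [lasso_path()] when `path` is NULL.
#' @return a `selected_subset` of size exactly `m` (criterion
#'   `"constrained"`).
#' @export
constrained_subset <- function(scores, y_perm, m, path = NULL,
                               rule = c("criterion", "truncate"), ...) {
  rule <- match.arg(rule)
  scores <- as.matrix(scores)
  K <- ncol(scores)
  stopifnot(m >= 1L, m <= K)
  gene_ids <- colnames(scores) %||% paste0("g", seq_len(K))
  y_perm <- check_binary_phenotype(y_perm)
  as_subset <- function(idx, lambda = NA_real_, loglik = NA_real_) {
    structure(list(gene_ids = gene_ids[idx], idx = idx, m = length(idx),
                   criterion = "constrained", score = NA_real_,
                   loglik = loglik, lambda = lambda),
              class = "selected_subset")
  }
  if (rule == "criterion") {
    if (is.null(path)) path <- lasso_path(scores, y_perm, ...)
    cand <- size_m_candidates(path, m)
    if (length(cand) > 0L) {
      lls <- vapply(cand, function(idx)
        fit_logistic(scores[, idx, drop = FALSE], y_perm,
                     warn = FALSE)$loglik, numeric(1L))
      best <- which.max(lls)
      return(as_subset(cand[[best]], loglik = lls[best]))
    }
    # no size-m candidate on this path: truncation fallback below
  }
  if (is.null(path)) {
    idx <- perm_constrained_idx(scores, y_perm, m, ...)[[as.character(m)]]
    return(as_subset(idx))
  }
  truncate_on_path(path, m, as_subset)
}

# truncation rule: largest lambda with >= m active genes, top-|beta|
truncate_on_path <- function(path, m, as_subset) {
  K <- length(path$gene_ids)
  sizes <- colSums(path$beta_grid != 0)
  sizes[path$lambda_grid == 0] <- K
  l <- max(which(sizes >= m))  # largest lambda with >= m active genes
  act <- if (path$lambda_grid[l] == 0) seq_len(K)
         else unname(which(path$beta_grid[, l] != 0))
  if (length(act) > m) {
    b <- abs(path$beta_grid[act, l])
    if (path$standardize) b <- b * path$sd[act]
    act <- sort(act[order(-b, seq_along(act))[seq_len(m)]])
  }
  as_subset(act, lambda = path$lambda_grid[l])
}

# distinct candidate subsets of size exactly m recorded on a path
size_m_candidates <- function(path, m) {
  unique(path$subsets[lengths(path$subsets) == m])
}

# LR statistics of the size-constrained null re-selection for each size in
# ms, for one permuted phenotype. Implements the "criterion" rule of
# constrained_subset() without building a full subset_path object: one
# glmnet fit over the standard grid, then for each m the distinct active
# sets of size exactly m are refit and the best log-likelihood kept
# (truncation fallback when the grid never has exactly m active genes).
perm_constrained_lr <- function(scores, yb, ms, ll0, nlambda = 100L,
                                lambda_min_ratio = 1e-4, standardize = TRUE,
                                thresh = 1e-6, sdv = NULL) {
  K <- ncol(scores)
  n <- nrow(scores)
  ms <- unique(as.integer(ms))
  out <- stats::setNames(numeric(length(ms)), as.character(ms))
  refit_lr <- function(idx) {
    fit <- fit_logistic(scores[, idx, drop = FALSE], yb, warn = FALSE)
    max(2 * (fit$loglik - ll0), 0)
  }
  if (all(ms >= K)) {
    out[] <- refit_lr(seq_len(K))
    return(out)
  }
  if (is.null(sdv)) sdv <- apply(scores, 2L, sd_pop)
  r0 <- yb - mean(yb)
  scale_j <- if (standardize) ifelse(sdv > 0, sdv, Inf) else rep(1, K)
  cors <- abs(drop(crossprod(scores, r0)) / scale_j)
  lmax <- max(cors) / n
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  # penalized part of the standard grid only: size-m < K candidates never
  # come from the lambda = 0 point (whose active set is all K genes)
  grid_dec <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  fit <- glmnet::glmnet(scores, yb, family = "binomial", lambda = grid_dec,
                        standardize = standardize, thresh = thresh,
                        maxit = 10^6)
  sizes <- fit$df
  for (m in ms) {
    if (m >= K) {
      out[as.character(m)] <- refit_lr(seq_len(K))
      next
    }
    cols <- which(sizes == m)
    if (length(cols) > 0L) {
      bm <- as.matrix(fit$beta[, cols, drop = FALSE])
      cand <- unique(lapply(seq_along(cols),
                            function(j) unname(which(bm[, j] != 0))))
      out[as.character(m)] <- max(vapply(cand, refit_lr, numeric(1L)))
    } else if (any(sizes >= m)) {
      # truncation fallback: largest lambda with >= m active genes
      l <- which(sizes >= m)[1L]
      act <- unname(which(fit$beta[, l] != 0))
      b <- abs(fit$beta[act, l])
      if (standardize) b <- b * sdv[act]
      act <- sort(act[order(-b, seq_along(act))[seq_len(m)]])
      out[as.character(m)] <- refit_lr(act)
    } else {
      # the penalized grid never activates m genes: pad the densest active
      # set with the remaining genes ranked by |score-residual correlation|
      act <- unname(which(fit$beta[, length(sizes)] != 0))
      rest <- setdiff(order(-cors), act)
      out[as.character(m)] <- refit_lr(sort(c(act, rest)[seq_len(m)]))
    }
  }
  out
}

# Size-constrained active sets for a (permuted) phenotype at one or more
# target sizes ms under the TRUNCATION rule, computed on the same decreasing
# lambda grid as lasso_path() but fitted in segments from lambda_max,
# stopping as soon as the largest requested size has been reached (the first
# grid point, in decreasing-lambda order, whose active set reaches size m is
# exactly the "largest lambda with size >= m"). Returns a list mapping
# as.character(m) to the index vector of the selected subset; results are
# identical to scanning the full recorded grid.
perm_constrained_idx <- function(scores, yb, ms, nlambda = 100L,
                                 lambda_min_ratio = 1e-4, standardize = TRUE,
                                 thresh = 1e-6) {
  K <- ncol(scores)
  n <- nrow(scores)
  ms <- sort(unique(as.integer(ms)))
  stopifnot(all(ms >= 1L), all(ms <= K))
  out <- stats::setNames(vector("list", length(ms)), as.character(ms))
  for (m in ms[ms >= K]) out[[as.character(m)]] <- seq_len(K)
  need <- ms[ms < K]
  if (length(need) == 0L) return(out)
  target <- max(need)
  sdv <- apply(scores, 2L, sd_pop)
  r0 <- yb - mean(yb)
  scale_j <- if (standardize) ifelse(sdv > 0, sdv, Inf) else rep(1, K)
  lmax <- max(abs(drop(crossprod(scores, r0)) / scale_j)) / n
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  grid_dec <- c(exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                        length.out = nlambda)), 0)
  seg_ends <- unique(pmin(c(15L, 40L, length(grid_dec)),
                          length(grid_dec)))
  fit <- NULL
  sizes <- NULL
  for (e in seg_ends) {
    fit <- glmnet::glmnet(scores, yb, family = "binomial",
                          lambda = grid_dec[seq_len(e)],
                          standardize = standardize, thresh = thresh,
                          maxit = 10^6)
    sizes <- fit$df
    sizes[fit$lambda == 0] <- K   # lambda = 0 model contains all genes
    if (any(sizes >= target)) break
  }
  beta <- fit$beta                # sparse K x (grid prefix)
  for (m in need) {
    col <- which(sizes >= m)[1L]
    act <- if (fit$lambda[col] == 0) seq_len(K)
           else unname(which(beta[, col] != 0))
    if (length(act) > m) {
      b <- abs(beta[act, col])
      if (standardize) b <- b * sdv[act]
      act <- sort(act[order(-b, seq_along(act))[seq_len(m)]])
    }
    out[[as.character(m)]] <- act
  }
  out
}
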