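# Gene-level scores: first principal component of centered SNP dosages.
#
# PCA is on the covariance (not correlation) of centered, unscaled dosages:
# genotypes are centered per SNP by subtracting the mean, never standardized.
# The score of a gene is the projection of its centered dosage block onto the
# top eigenvector of the block's sample covariance.

#' Center a dosage block, imputing missing genotypes by the SNP mean
#'
#' Missing cells are replaced by the per-SNP mean of the observed dosages,
#' then every column is centered to mean zero.
#'
#' @param block numeric matrix `n x p` of dosages with `NA` for missing.
#' @return centered numeric matrix of the same shape; every column mean 0.
#' @export
center_and_impute <- function(block) {
  block <- as.matrix(block)
  if (nrow(block) < 2L) stop("need at least 2 samples")
  nobs <- colSums(!is.na(block))
  if (any(nobs == 0L)) {
    ids <- colnames(block)[nobs == 0L] %||% paste0("column ", which(nobs == 0L))
    stop("SNP with all genotypes missing: ", paste(ids, collapse = ", "))
  }
  mu <- colMeans(block, na.rm = TRUE)
  idx <- which(is.na(block), arr.ind = TRUE)
  if (nrow(idx)) block[idx] <- mu[idx[, 2L]]
  sweep(block, 2L, colMeans(block), "-")
}

# Iterative-PCA imputation: alternate between rank-1 reconstruction of the
# centered block and re-imputation of the missing cells, starting from mean
# imputation. Offered as an alternative to plain mean imputation for blocks
# with substantial missingness.
center_and_impute_iterative <- function(block, max_iter = 50L, tol = 1e-8) {
  block <- as.matrix(block)
  miss <- is.na(block)
  x <- center_and_impute(block)
  if (!any(miss)) return(x)
  for (it in seq_len(max_iter)) {
    f <- fpc_score(x)
    recon <- outer(f$score, f$loading)
    delta <- max(abs(recon[miss] - x[miss]))
    x[miss] <- recon[miss]
    x <- sweep(x, 2L, colMeans(x), "-")
    if (delta < tol) break
  }
  x
}

#' First-principal-component score of a centered SNP block
#'
#' The loading is the top eigenvector of the sample covariance (denominator
#' `n - 1`) of the centered block; the score is the block projected onto it.
#' The loading has unit Euclidean norm and its entry of largest absolute
#' value is made positive, which fixes the otherwise arbitrary sign
#' (downstream likelihood-ratio statistics are sign-invariant). For a
#' single-SNP gene the score is the centered column itself. The eigenvector
#' is computed from the `p x p` covariance when `p <= n`, otherwise from the
#' `n x n` Gram matrix.
#'
#' @param block centered numeric matrix `n x p` (see [center_and_impute()]).
#' @return list with `score` (length n), `loading` (length p, unit norm) and
#'   `explained_variance` (top eigenvalue).
#' @export
fpc_score <- function(block) {
  block <- as.matrix(block)
  n <- nrow(block)
  p <- ncol(block)
  stopifnot(p >= 1L, n >= 2L)
  if (max(abs(colMeans(block))) > 1e-8)
    stop("block must be centered (see center_and_impute)")
  if (p == 1L) {
    v <- drop(block)
    ev <- sum(v^2) / (n - 1)
    if (ev < 1e-12) warning("zero-variance gene block: score is all zeros")
    return(list(score = v, loading = 1, explained_variance = ev))
  }
  if (p <= n) {
    e <- eigen(crossprod(block) / (n - 1), symmetric = TRUE)
    ev <- e$values[1L]
    loading <- e$vectors[, 1L]
  } else {
    e <- eigen(tcrossprod(block) / (n - 1), symmetric = TRUE)
    ev <- e$values[1L]
    loading <- drop(crossprod(block, e$vectors[, 1L]))
    nl <- sqrt(sum(loading^2))
    loading <- if (nl > 0) loading / nl else rep(0, p)
  }
  if (ev < 1e-12) {
    warning("zero-variance gene block: score is all zeros")
    return(list(score = rep(0, n), loading = c(1, rep(0, p - 1L)),
                explained_variance = 0))
  }
  i <- which.max(abs(loading))
  if (loading[i] < 0) loading <- -loading
  list(score = drop(block %*% loading), loading = loading,
       explained_variance = ev)
}

#' Build the gene-score matrix for a set of genes
#'
#' Computes the FPC score of every requested gene from the dataset's dosages
#' and the SNP-to-gene map, reducing the predictor count from the total
#' number of SNPs to the number of genes.
#'
#' @param ds a [genotype_dataset()].
#' @param gm a [map_snps_to_genes()] gene map (or any list with an
#'   `assignments` element).
#' @param genes character vector of gene ids; every gene must have at least
#'   one mapped SNP.
#' @param impute `"mean"` (default) or `"iterative"` missing-data handling.
#' @return object of class `gene_scores`: list with `scores` (`n x K` matrix,
#'   one column per gene, each column mean 0), `loadings` (named list of
#'   unit-norm vectors) and `explained_variance` (named numeric).
#' @export
build_gene_scores <- function(ds, gm, genes = names(gm$assignments),
                              impute = c("mean", "iterative")) {
  impute <- match.arg(impute)
  missing_genes <- setdiff(genes, names(gm$assignments))
  if (length(missing_genes))
    stop("genes with no mapped SNPs: ", paste(missing_genes, collapse = ", "))
  n <- nrow(ds$dosages)
  scores <- matrix(0, n, length(genes), dimnames = list(ds$samples, genes))
  loadings <- vector("list", length(genes))
  names(loadings) <- genes
  ev <- stats::setNames(numeric(length(genes)), genes)
  for (g in genes) {
    block <- ds$dosages[, gm$assignments[[g]], drop = FALSE]
    centered <- if (impute == "mean") center_and_impute(block)
                else center_and_impute_iterative(block)
    f <- fpc_score(centered)
    scores[, g] <- f$score
    loadings[[g]] <- stats::setNames(f$loading, colnames(block))
    ev[g] <- f$explained_variance
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev), class = "gene_scores")
}

#' Export a gene-score matrix as TSV
#'
#' @param gs a [build_gene_scores()] object.
#' @param path output path; samples in rows, genes in columns.
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(gs, path) {
  df <- data.frame(sample_id = rownames(gs$scores), gs$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
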