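#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded package functions never perturb the global random stream. A `NULL`
#' seed evaluates `code` under the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw reproducible sub-seeds from a master seed
#'
#' All randomness in multi-replicate or multi-permutation routines flows from
#' one master seed through sub-seeds drawn here, so replicates and
#' permutations form named, reproducible streams.
#'
#' @param k number of sub-seeds.
#' @param seed master seed (`NULL` = current stream).
#' @return integer vector of length `k`, each < 2^31.
#' @export
draw_seeds <- function(k, seed = NULL) {
  with_seed(seed, sample.int(2147483646L, k))
}

#' Generate a shared phenotype-permutation ensemble
#'
#' Returns an `n x B` matrix whose column `b` is a uniformly random
#' permutation of `1:n`. One such ensemble is shared across all pathways and
#' methods of a run so that permutation-based FDR/FWER exceedances (and
#' paired method comparisons) are computed on a common set of shuffles.
#'
#' @param n number of samples.
#' @param B number of permutations.
#' @param seed integer seed or `NULL`.
#' @return integer matrix `n x B` of permuted sample indices.
#' @export
make_permutations <- function(n, B, seed = NULL) {
  stopifnot(n >= 2, B >= 1)
  with_seed(seed, vapply(seq_len(B), function(b) sample.int(n), integer(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
check_binary_phenotype <- function(y) {
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("phenotype must be a binary 0/1 vector with no missing values")
  if (length(unique(y)) < 2L)
    stop("both phenotype classes (cases and controls) must be present")
  invisible(as.integer(y))
}
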