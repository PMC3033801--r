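# Case-control genotype simulator: haplotype pools sampled under HWE, a
# multiplicative relative-risk disease model, and the three pathway patterns
# (gene counts, causal-SNP MAFs and estimated relative risks) used in the
# power/type-I-error studies.
#
# Real haplotype frequencies estimated from control samples are not
# distributable; the pool builder therefore offers parametric LD models
# (independent SNPs, or first-order correlation chains within blocks) while
# preserving the pattern MAF/ERR tables exactly.

#' Construct a haplotype pool from an explicit haplotype table
#'
#' Accepts a given haplotype pool (e.g. externally estimated frequencies):
#' haplotypes are 0/1 vectors (1 = minor allele) with sampling probabilities
#' proportional to `freqs`.
#'
#' @param haplotypes 0/1 matrix, one haplotype per row.
#' @param freqs nonnegative weights, one per haplotype (normalized to sum 1).
#' @return object of class `haplotype_pool`.
#' @export
haplotype_pool <- function(haplotypes, freqs) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(all(haplotypes %in% c(0, 1)), length(freqs) == nrow(haplotypes),
            all(freqs >= 0), sum(freqs) > 0)
  freqs <- freqs / sum(freqs)
  mafs <- drop(freqs %*% haplotypes)
  structure(list(model = "explicit", p = ncol(haplotypes),
                 haplotypes = haplotypes, freqs = freqs, mafs = mafs),
            class = "haplotype_pool")
}

#' Build a parametric haplotype pool
#'
#' Two LD models are available. `independent`: alleles at each locus are
#' independent Bernoulli draws with the given minor-allele frequencies.
#' `block`: loci are partitioned into consecutive blocks of `block_size`;
#' within a block, alleles follow a first-order correlation chain with
#' target pairwise correlation `r` between neighbours (blocks are mutually
#' independent). For `p <= 10` loci the implied haplotype distribution is
#' also enumerated explicitly (`haplotypes`/`freqs`).
#'
#' @param mafs minor-allele frequencies in (0, 0.5].
#' @param ld LD model: `list(model = "independent")` (default) or
#'   `list(model = "block", r = <correlation>, block_size = <int>,
#'   cap_r = <logical>)`. The attainable correlation between two Bernoulli
#'   alleles is bounded by their frequency mismatch (Frechet bound, about
#'   `sqrt(maf1/maf2)` for rare-vs-common pairs); with `cap_r = TRUE` each
#'   neighbour pair's correlation is capped at 99.5% of its bound instead of
#'   erroring, mirroring the frequency dependence of empirical LD.
#' @return object of class `haplotype_pool`.
#' @export
build_pool <- function(mafs, ld = list(model = "independent")) {
  stopifnot(all(mafs > 0), all(mafs <= 0.5))
  model <- match.arg(ld$model, c("independent", "block"))
  p <- length(mafs)
  pool <- list(model = model, p = p, mafs = mafs)
  if (model == "block") {
    r <- ld$r
    bs <- as.integer(ld$block_size %||% p)
    stopifnot(is.numeric(r), r >= 0, r < 1, bs >= 1L)
    pool$r <- r
    pool$block_size <- bs
    pool$blocks <- split(seq_len(p), (seq_len(p) - 1L) %/% bs)
    # chain feasibility: P(1,1) of each neighbour pair must be a valid joint
    # probability; r_pairs holds the correlation actually used per pair
    pool$r_pairs <- lapply(pool$blocks, function(blk) {
      if (length(blk) < 2L) return(numeric(0))
      a <- mafs[blk[-length(blk)]]
      b <- mafs[blk[-1L]]
      rmax <- (pmin(a, b) - a * b) / sqrt(a * (1 - a) * b * (1 - b))
      if (isTRUE(ld$cap_r)) return(pmin(r, 0.995 * rmax))
      if (any(r > rmax + 1e-12))
        stop("infeasible (maf, r) combination in block model")
      rep(r, length(a))
    })
  }
  pool <- structure(pool, class = "haplotype_pool")
  if (p <= 10L) {
    hap <- as.matrix(expand.grid(rep(list(c(0L, 1L)), p)))[, seq_len(p),
                                                           drop = FALSE]
    dimnames(hap) <- NULL
    pool$haplotypes <- hap
    pool$freqs <- apply(hap, 1L, function(h) haplotype_prob(pool, h))
  }
  pool
}

# probability of one haplotype under a parametric pool
haplotype_prob <- function(pool, h) {
  m <- pool$mafs
  if (pool$model == "independent")
    return(prod(ifelse(h == 1, m, 1 - m)))
  pr <- 1
  for (k in seq_along(pool$blocks)) {
    blk <- pool$blocks[[k]]
    rp <- pool$r_pairs[[k]]
    pr <- pr * (if (h[blk[1L]] == 1) m[blk[1L]] else 1 - m[blk[1L]])
    for (i in seq_along(blk)[-1L]) {
      a <- m[blk[i - 1L]]; b <- m[blk[i]]
      p11 <- a * b + rp[i - 1L] * sqrt(a * (1 - a) * b * (1 - b))
      cond1 <- p11 / a                    # P(1 | prev = 1)
      cond0 <- (b - p11) / (1 - a)        # P(1 | prev = 0)
      pc <- if (h[blk[i - 1L]] == 1) cond1 else cond0
      pr <- pr * (if (h[blk[i]] == 1) pc else 1 - pc)
    }
  }
  pr
}

# draw n_hap haplotypes (rows) from a pool under the current RNG stream
sample_haplotypes <- function(pool, n_hap) {
  p <- pool$p
  if (pool$model == "explicit") {
    idx <- sample.int(nrow(pool$haplotypes), n_hap, replace = TRUE,
                      prob = pool$freqs)
    return(pool$haplotypes[idx, , drop = FALSE])
  }
  H <- matrix(0L, n_hap, p)
  if (pool$model == "independent") {
    H[] <- stats::rbinom(n_hap * p, 1L, rep(pool$mafs, each = n_hap))
    return(H)
  }
  m <- pool$mafs
  for (k in seq_along(pool$blocks)) {
    blk <- pool$blocks[[k]]
    rp <- pool$r_pairs[[k]]
    H[, blk[1L]] <- stats::rbinom(n_hap, 1L, m[blk[1L]])
    for (i in seq_along(blk)[-1L]) {
      a <- m[blk[i - 1L]]; b <- m[blk[i]]
      p11 <- a * b + rp[i - 1L] * sqrt(a * (1 - a) * b * (1 - b))
      cond <- ifelse(H[, blk[i - 1L]] == 1L, p11 / a, (b - p11) / (1 - a))
      H[, blk[i]] <- stats::rbinom(n_hap, 1L, cond)
    }
  }
  H
}

#' Sample genotype dosages from a haplotype pool under HWE
#'
#' Each individual is formed from two independent haplotype draws
#' (Hardy-Weinberg equilibrium); the dosage is the minor-allele count.
#'
#' @param pool a [build_pool()] or [haplotype_pool()] object.
#' @param n number of individuals.
#' @param seed integer seed or `NULL` (use the current RNG stream).
#' @return integer dosage matrix `n x p`.
#' @export
sample_genotypes <- function(pool, n, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), n >= 1L)
  with_seed(seed, sample_haplotypes(pool, n) + sample_haplotypes(pool, n))
}

#' Multiplicative relative-risk disease probabilities
#'
#' `P(affected | g) = base_prevalence * prod_s rr_s^{g_s}` over the causal
#' SNPs. Errors if the probability exceeds 1 for the maximal genotype.
#'
#' @param dosages dosage matrix.
#' @param causal data.frame with columns `snp` (column index) and `rr`.
#' @param base_prevalence baseline disease probability (default 0.05).
#' @return vector of disease probabilities.
#' @export
disease_prob <- function(dosages, causal, base_prevalence = 0.05) {
  # maximal genotype: dosage 2 at every risk-increasing causal SNP
  if (base_prevalence * prod(pmax(causal$rr, 1)^2) > 1)
    stop("disease probability exceeds 1 for the maximal genotype; ",
         "lower base_prevalence")
  pr <- rep(base_prevalence, nrow(dosages))
  for (i in seq_len(nrow(causal)))
    pr <- pr * causal$rr[i]^dosages[, causal$snp[i]]
  pr
}

#' Assign disease status under the multiplicative model
#'
#' Bernoulli draw of affected status for each individual with probability
#' [disease_prob()].
#'
#' @inheritParams disease_prob
#' @param seed integer seed or `NULL`.
#' @return integer 0/1 status vector.
#' @export
assign_phenotype <- function(dosages, causal, base_prevalence = 0.05,
                             seed = NULL) {
  pr <- disease_prob(dosages, causal, base_prevalence)
  with_seed(seed, stats::rbinom(length(pr), 1L, pr))
}

# Rejection sampling to exact case/control counts. pools: list of per-gene
# haplotype pools (columns concatenated in order); causal$snp indexes the
# concatenated dosage matrix.
simulate_case_control <- function(pools, causal, base_prevalence,
                                  n_cases, n_controls, seed = NULL) {
  with_seed(seed, {
    need_batch <- max(1000L,
                      ceiling(1.3 * n_cases / base_prevalence / 10) * 10)
    cases <- NULL
    controls <- NULL
    while (is.null(cases) || nrow(cases) < n_cases ||
           nrow(controls) < n_controls) {
      G <- do.call(cbind, lapply(pools, sample_haplotypes, n_hap = need_batch)) +
        do.call(cbind, lapply(pools, sample_haplotypes, n_hap = need_batch))
      status <- if (nrow(causal) > 0)
        assign_phenotype(G, causal, base_prevalence)
      else stats::rbinom(need_batch, 1L, base_prevalence)
      cases <- rbind(cases, G[status == 1L, , drop = FALSE])
      controls <- rbind(controls, G[status == 0L, , drop = FALSE])
    }
    rbind(cases[seq_len(n_cases), , drop = FALSE],
          controls[seq_len(n_controls), , drop = FALSE])
  })
}

#' Combined relative risk of a causal-SNP set
#'
#' Product of the attenuated per-allele relative risks `f * err_i`, rounded
#' for reporting. With the four pattern-1 estimated relative risks this gives
#' 1.46 at `f = 1` and 1.24 at `f = 0.96`.
#'
#' @param errs vector of estimated relative risks.
#' @param f attenuation factor in (0, 1].
#' @param digits rounding for reporting (default 2).
#' @return the combined relative risk.
#' @export
combined_rr <- function(errs, f = 1, digits = 2) {
  stopifnot(f > 0, f <= 1, all(errs > 0))
  round(prod(f * errs), digits)
}

#' Pick representative causal SNPs from association results
#'
#' Within every gene whose gene-level p-value is at or below `p_thresh`, the
#' SNPs with p-value at or below `p_thresh` are clustered by single linkage
#' on pairwise dosage r-squared at threshold `r2_thresh`; the smallest-p SNP
#' of each cluster is declared causal. r-squared is computed on dosages
#' (composite LD), which is what unphased data affords.
#'
#' @param snp_pvals per-SNP p-values aligned with `dosages` columns.
#' @param dosages dosage matrix.
#' @param gene_map a [map_snps_to_genes()] gene map.
#' @param gene_pvals named per-gene p-values; if `NULL`, computed from `y`
#'   as the chi-square p-value of each gene's FPC likelihood-ratio test.
#' @param y binary phenotype (required when `gene_pvals` is `NULL`).
#' @param p_thresh significance threshold (default 0.05).
#' @param r2_thresh LD clustering threshold (default 0.8).
#' @return integer vector of causal SNP column indices.
#' @export
select_causal_snps <- function(snp_pvals, dosages, gene_map,
                               gene_pvals = NULL, y = NULL,
                               p_thresh = 0.05, r2_thresh = 0.8) {
  dosages <- as.matrix(dosages)
  stopifnot(length(snp_pvals) == ncol(dosages))
  if (is.null(gene_pvals)) {
    if (is.null(y)) stop("supply gene_pvals or y")
    gene_pvals <- vapply(gene_map$assignments, function(idx) {
      block <- center_and_impute(dosages[, idx, drop = FALSE])
      f <- suppressWarnings(fpc_score(block))
      T <- logistic_lr(matrix(f$score), y)
      stats::pchisq(T, 1L, lower.tail = FALSE)
    }, numeric(1L))
  }
  causal <- integer(0)
  for (g in names(gene_map$assignments)) {
    if (gene_pvals[[g]] > p_thresh) next
    idx <- gene_map$assignments[[g]]
    sig <- idx[snp_pvals[idx] <= p_thresh]
    if (length(sig) == 0L) next
    if (length(sig) == 1L) { causal <- c(causal, sig); next }
    r2 <- suppressWarnings(stats::cor(dosages[, sig, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    adj <- r2 >= r2_thresh
    comp <- single_linkage_components(adj)
    for (cl in unique(comp)) {
      members <- sig[comp == cl]
      causal <- c(causal, members[which.min(snp_pvals[members])])
    }
  }
  sort(causal)
}

# connected components of an adjacency matrix (single-linkage clusters)
single_linkage_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# -- pathway patterns --------------------------------------------------------

PATTERNS <- list(
  pattern1 = list(
    label = "TNFR2 signaling (small pathway)",
    n_genes = 15L, n_snps = 159L, n_assoc = 2L,
    causal_per_gene = c(2L, 2L),
    causal_maf = c(0.340, 0.416, 0.298, 0.317),
    causal_err = c(1.070, 1.081, 1.117, 1.130)),
  pattern2 = list(
    label = "fructose/mannose metabolism (medium pathway)",
    n_genes = 35L, n_snps = 339L, n_assoc = 4L,
    causal_per_gene = c(2L, 2L, 1L, 1L),
    causal_maf = c(0.163, 0.353, 0.359, 0.359, 0.424, 0.332),
    causal_err = c(1.113, 1.077, 1.063, 1.101, 1.105, 1.088)),
  pattern3 = list(
    label = "cytokine-cytokine receptor interaction (large pathway)",
    n_genes = 208L, n_snps = 1957L, n_assoc = 19L,
    causal_per_gene = c(3L, rep(2L, 18L)),
    causal_maf = c(0.409, 0.491, 0.491, 0.275, 0.397, 0.315, 0.210, 0.073,
                   0.372, 0.415, 0.281, 0.219, 0.472, 0.305, 0.355, 0.435,
                   0.112, 0.323, 0.373, 0.044, 0.063, 0.227, 0.430, 0.070,
                   0.161, 0.355, 0.161, 0.034, 0.156, 0.417, 0.420, 0.169,
                   0.210, 0.175, 0.183, 0.269, 0.194, 0.177, 0.499),
    causal_err = c(1.100, 1.065, 1.064, 1.090, 1.055, 1.086, 1.167, 1.172,
                   1.057, 1.084, 1.141, 1.081, 1.095, 1.149, 1.072, 1.092,
                   1.087, 1.062, 1.132, 1.134, 1.162, 1.094, 1.060, 1.247,
                   1.078, 1.062, 1.096, 1.249, 1.123, 1.070, 1.089, 1.073,
                   1.087, 1.093, 1.074, 1.064, 1.087, 1.123, 1.071))
)

#' Simulation pattern descriptor
#'
#' The three built-in patterns describe a small (15 genes / 159 SNPs, 2
#' associated genes, 4 causal SNPs), medium (35/339, 4, 6) and large
#' (208/1957, 19, 39) pathway, with the causal-SNP minor-allele frequencies
#' and per-allele estimated relative risks fixed to the pattern tables. SNPs
#' are split over genes as evenly as possible; the first `n_assoc` genes are
#' the associated ones, and causal SNPs are spaced 5 loci apart inside their
#' gene (so each falls in a different LD block under the default block
#' model). Non-causal MAFs are drawn per replicate from Uniform(0.05, 0.5).
#'
#' @param name `"pattern1"`, `"pattern2"` or `"pattern3"`, or a list with the
#'   same fields for a custom pattern.
#' @param n_cases,n_controls sample sizes (default 1350 each).
#' @param ld default LD model for replicates: a first-order correlation
#'   chain spanning each gene with neighbour correlation r = 0.9 (neighbour
#'   r-squared 0.81, at the conventional strong-LD threshold, decaying with
#'   distance; causal SNPs, spaced 5 loci apart, then sit in distinct
#'   strong-LD groups with pairwise r-squared about 0.33).
#' @return object of class `sim_pattern`.
#' @export
sim_pattern <- function(name = c("pattern1", "pattern2", "pattern3"),
                        n_cases = 1350L, n_controls = 1350L,
                        ld = list(model = "block", r = 0.9, cap_r = TRUE)) {
  pat <- if (is.list(name)) name else PATTERNS[[match.arg(name)]]
  stopifnot(length(pat$causal_maf) == sum(pat$causal_per_gene),
            length(pat$causal_err) == length(pat$causal_maf),
            all(pat$causal_maf > 0), all(pat$causal_maf <= 0.5),
            all(pat$causal_err > 0),
            pat$n_assoc == length(pat$causal_per_gene))
  base <- pat$n_snps %/% pat$n_genes
  rem <- pat$n_snps %% pat$n_genes
  gene_sizes <- rep(base, pat$n_genes) + c(rep(1L, rem),
                                           rep(0L, pat$n_genes - rem))
  offsets <- cumsum(c(0L, gene_sizes[-pat$n_genes]))
  # causal SNP global indices: 5 loci apart within each associated gene
  causal_idx <- integer(0)
  for (g in seq_len(pat$n_assoc)) {
    cnt <- pat$causal_per_gene[g]
    # space causal SNPs 5 loci apart (distinct strong-LD groups under the
    # default chain model), compressing when the gene is too short
    spacing <- if (cnt == 1L) 1L
               else max(1L, min(5L, (gene_sizes[g] - 1L) %/% (cnt - 1L)))
    within <- seq(1L, by = spacing, length.out = cnt)
    stopifnot(max(within) <= gene_sizes[g])
    causal_idx <- c(causal_idx, offsets[g] + within)
  }
  structure(c(pat, list(name = if (is.list(name)) pat$label else match.arg(name),
                        gene_sizes = gene_sizes, gene_offsets = offsets,
                        causal_idx = causal_idx, n_cases = as.integer(n_cases),
                        n_controls = as.integer(n_controls), ld = ld)),
            class = "sim_pattern")
}

#' @export
print.sim_pattern <- function(x, ...) {
  cat(sprintf("sim_pattern %s: %d genes (%d SNPs), %d associated genes, %d causal SNPs\n",
              x$name, x$n_genes, x$n_snps, x$n_assoc, length(x$causal_idx)))
  invisible(x)
}

# Draw the per-SNP minor-allele frequencies of a pattern replicate under the
# current RNG stream. Independent model: U(0.05, 0.5) per SNP (causal SNPs
# overridden to their pattern MAFs by the caller). Block model: SNPs in
# strong LD necessarily have similar allele frequencies (the attainable
# correlation between Bernoulli alleles shrinks as their frequencies
# diverge), so each block shares a base MAF -- the causal SNP's pattern MAF
# when the block holds one, else U(0.05, 0.5) -- with members jittered
# multiplicatively by +/-5% (clamped to [0.02, 0.5]), which keeps the
# default target correlation feasible.
draw_pattern_mafs <- function(pattern, ld) {
  P <- pattern$n_snps
  if (!identical(ld$model, "block"))
    return(stats::runif(P, 0.05, 0.5))
  mafs <- numeric(P)
  for (g in seq_len(pattern$n_genes)) {
    idx <- pattern$gene_offsets[g] + seq_len(pattern$gene_sizes[g])
    bs <- as.integer(ld$block_size %||% length(idx))
    for (blk in split(idx, (seq_along(idx) - 1L) %/% bs)) {
      cz <- intersect(blk, pattern$causal_idx)
      base <- if (length(cz))
        pattern$causal_maf[match(cz[1L], pattern$causal_idx)]
      else stats::runif(1L, 0.05, 0.5)
      mafs[blk] <- pmin(pmax(base * stats::runif(length(blk), 0.95, 1.05),
                             0.02), 0.5)
    }
  }
  mafs
}

#' Simulate one case-control replicate of a pathway pattern
#'
#' Draws per-gene haplotype pools (causal SNPs at their pattern MAFs,
#' non-causal MAFs from Uniform(0.05, 0.5)), samples genotypes under HWE, and
#' assigns disease status under the multiplicative relative-risk model with
#' per-allele risks `f * ERR`, retaining exactly `n_cases` cases and
#' `n_controls` controls by rejection sampling. With `null = TRUE` no SNP is
#' causal: every individual's disease probability equals the baseline, so
#' case and control genotypes are exchangeable draws from the pool and the
#' labels are assigned directly.
#'
#' @param pattern a [sim_pattern()].
#' @param f attenuation factor applied to every estimated relative risk.
#' @param n_cases,n_controls override the pattern's sample sizes.
#' @param ld override the pattern's LD model.
#' @param base_prevalence baseline disease probability (default 0.05).
#' @param null simulate under the global null (no causal SNPs).
#' @param seed integer seed or `NULL`.
#' @return object of class `sim_replicate`: `ds` (a [genotype_dataset()]),
#'   `genes` (gene position table), `gene_map`, and `truth` (associated gene
#'   ids, causal SNP ids/indices, per-SNP relative risks).
#' @export
simulate_replicate <- function(pattern, f = 1, n_cases = pattern$n_cases,
                               n_controls = pattern$n_controls,
                               ld = pattern$ld, base_prevalence = 0.05,
                               null = FALSE, seed = NULL) {
  stopifnot(inherits(pattern, "sim_pattern"), f > 0, f <= 1)
  with_seed(seed, {
    P <- pattern$n_snps
    mafs <- draw_pattern_mafs(pattern, ld)
    causal <- if (null) {
      data.frame(snp = integer(0), rr = numeric(0))
    } else {
      mafs[pattern$causal_idx] <- pattern$causal_maf
      data.frame(snp = pattern$causal_idx, rr = f * pattern$causal_err)
    }
    pools <- lapply(seq_len(pattern$n_genes), function(g) {
      idx <- pattern$gene_offsets[g] + seq_len(pattern$gene_sizes[g])
      build_pool(mafs[idx], ld)
    })
    n <- n_cases + n_controls
    if (null) {
      dos <- do.call(cbind, lapply(pools, sample_haplotypes, n_hap = n)) +
        do.call(cbind, lapply(pools, sample_haplotypes, n_hap = n))
    } else {
      dos <- simulate_case_control(pools, causal, base_prevalence,
                                   n_cases, n_controls)
    }
    y <- rep(c(1L, 0L), times = c(n_cases, n_controls))
    gene_ids <- sprintf("g%03d", seq_len(pattern$n_genes))
    gene_of_snp <- rep(seq_len(pattern$n_genes), times = pattern$gene_sizes)
    within <- sequence(pattern$gene_sizes)
    pos <- gene_of_snp * 10^6 + (within - 1L) * 1000L + 1L
    snps <- data.frame(
      snp_id = sprintf("%s_snp%02d", gene_ids[gene_of_snp], within),
      chrom = "1", pos = pos, minor_allele = "A", major_allele = "G",
      stringsAsFactors = FALSE)
    ds <- genotype_dataset(dos, y, snps)
    genes <- data.frame(
      gene_id = gene_ids, chrom = "1",
      start = seq_len(pattern$n_genes) * 10^6 + 1L,
      end = seq_len(pattern$n_genes) * 10^6 + 1L +
        (pattern$gene_sizes - 1L) * 1000L,
      stringsAsFactors = FALSE)
    gene_map <- structure(
      list(assignments = stats::setNames(
             lapply(seq_len(pattern$n_genes), function(g)
               pattern$gene_offsets[g] + seq_len(pattern$gene_sizes[g])),
             gene_ids),
           unmapped = integer(0), n_snps = P),
      class = "gene_map")
    truth <- list(
      assoc_genes = if (null) character(0) else
        gene_ids[seq_len(pattern$n_assoc)],
      causal_idx = causal$snp,
      causal_snps = snps$snp_id[causal$snp],
      rr = causal$rr)
    structure(list(ds = ds, genes = genes, gene_map = gene_map,
                   truth = truth, pattern_name = pattern$name, f = f),
              class = "sim_replicate")
  })
}
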