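# Haplotype pools, HWE genotype sampling, the multiplicative disease model
# and the pattern fixtures.

test_that("explicit pool enumeration for tiny cases", {
  p1 <- build_pool(0.3)
  expect_equal(sort(p1$freqs), c(0.3, 0.7))
  expect_equal(p1$haplotypes[order(p1$freqs), , drop = FALSE],
               matrix(c(1L, 0L)))
  p2 <- build_pool(c(0.5, 0.5))
  expect_equal(p2$freqs, rep(0.25, 4))
  # block pool frequencies sum to 1 and match target MAFs
  pb <- build_pool(c(0.3, 0.3, 0.3), list(model = "block", r = 0.9))
  expect_equal(sum(pb$freqs), 1, tolerance = 1e-12)
  expect_equal(drop(pb$freqs %*% pb$haplotypes), rep(0.3, 3),
               tolerance = 1e-12)
  expect_error(build_pool(c(0.05, 0.5), list(model = "block", r = 0.9)),
               "infeasible")
  # capped variant is feasible and bounded by the target
  pc <- build_pool(c(0.05, 0.5), list(model = "block", r = 0.9, cap_r = TRUE))
  expect_lte(pc$r_pairs[[1]][1], 0.9)
})

test_that("block model realizes the target allele correlation", {
  pool <- build_pool(c(0.3, 0.3), list(model = "block", r = 0.9))
  H <- pathfpc:::with_seed(81, pathfpc:::sample_haplotypes(pool, 1e5))
  expect_equal(cor(H[, 1], H[, 2])^2, 0.81, tolerance = 0.05)
  expect_equal(colMeans(H), c(0.3, 0.3), tolerance = 0.01)
})

test_that("HWE genotype sampling: frequencies, mean dosage, determinism", {
  pool <- build_pool(0.5)
  G <- sample_genotypes(pool, 20000, seed = 82)
  tab <- table(factor(G, levels = 0:2)) / 20000
  sd3 <- 3 * sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(tab[["0"]] - 0.25), sd3)
  expect_lt(abs(tab[["1"]] - 0.50), 3 * sqrt(0.5 * 0.5 / 20000))
  expect_lt(abs(tab[["2"]] - 0.25), sd3)
  pool2 <- build_pool(0.2)
  G2 <- sample_genotypes(pool2, 20000, seed = 83)
  expect_lt(abs(mean(G2) - 0.4), 3 * sqrt(2 * 0.2 * 0.8 / 20000))
  expect_identical(sample_genotypes(pool2, 50, seed = 9),
                   sample_genotypes(pool2, 50, seed = 9))
})

test_that("HWE goodness of fit holds for nearly all simulated SNPs", {
  sim <- simulate_replicate(sim_pattern("pattern1", 400, 400), null = TRUE,
                            n_cases = 400, n_controls = 400,
                            ld = list(model = "independent"), seed = 84)
  pvals <- apply(sim$ds$dosages, 2, function(g) {
    n <- length(g)
    phat <- mean(g) / 2
    exp_counts <- n * c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
    obs <- tabulate(g + 1, 3)
    keep <- exp_counts > 0
    pchisq(sum((obs[keep] - exp_counts[keep])^2 / exp_counts[keep]),
           df = 1, lower.tail = FALSE)
  })
  expect_gte(mean(pvals > 0.001), 0.95)
})

test_that("multiplicative disease model: null KS and allelic odds ratio", {
  pool <- build_pool(0.3)
  # no causal SNPs: case and control dosage distributions coincide
  sim0 <- simulate_replicate(sim_pattern("pattern1", 300, 300), null = TRUE,
                             n_cases = 300, n_controls = 300,
                             ld = list(model = "independent"), seed = 85)
  expect_gt(suppressWarnings(
    ks.test(sim0$ds$dosages[sim0$ds$y == 1, 1],
            sim0$ds$dosages[sim0$ds$y == 0, 1])$p.value), 0.01)
  # one causal SNP with rr = 2 at low prevalence: allelic OR ~ RR
  G <- sample_genotypes(pool, 60000, seed = 86)
  causal <- data.frame(snp = 1L, rr = 2)
  status <- assign_phenotype(G, causal, base_prevalence = 0.02, seed = 87)
  a_case <- sum(G[status == 1]);  u_case <- 2 * sum(status == 1) - a_case
  a_ctrl <- sum(G[status == 0]);  u_ctrl <- 2 * sum(status == 0) - a_ctrl
  or <- (a_case / u_case) / (a_ctrl / u_ctrl)
  expect_equal(or, 2, tolerance = 0.15)
  # probability > 1 guard
  expect_error(disease_prob(G, data.frame(snp = 1L, rr = 10),
                            base_prevalence = 0.5), "lower base_prevalence")
})

test_that("combined relative risk reproduces the published arithmetic", {
  errs <- sim_pattern("pattern1")$causal_err
  expect_equal(combined_rr(errs, 1), 1.46)
  expect_equal(combined_rr(errs, 0.96), 1.24)
  expect_equal(combined_rr(c(1, 1, 1), 1), 1)
})

test_that("causal-SNP selection clusters by single linkage on r2", {
  set.seed(88)
  base <- rbinom(400, 2, 0.3)
  # rsA and rsB identical (r2 = 1), rsC independent
  dos <- cbind(rsA = base, rsB = base, rsC = rbinom(400, 2, 0.3))
  gm <- structure(list(assignments = list(gene = 1:3), unmapped = integer(0),
                       n_snps = 3L), class = "gene_map")
  picked <- select_causal_snps(c(0.01, 0.04, 0.03), dos, gm,
                               gene_pvals = c(gene = 0.01))
  expect_equal(picked, c(1L, 3L))   # one per cluster, smallest p wins
  # independent pair both significant -> both causal
  picked2 <- select_causal_snps(c(0.01, 0.04), dos[, c(1, 3)],
                                structure(list(assignments = list(g = 1:2),
                                               unmapped = integer(0),
                                               n_snps = 2L),
                                          class = "gene_map"),
                                gene_pvals = c(g = 0.01))
  expect_equal(picked2, c(1L, 2L))
  # non-significant gene contributes nothing
  picked3 <- select_causal_snps(c(0.01, 0.04, 0.03), dos, gm,
                                gene_pvals = c(gene = 0.2))
  expect_equal(picked3, integer(0))
  # chain A-B, B-C linked, A-C not: single linkage -> one cluster of 3
  adj <- matrix(c(TRUE, TRUE, FALSE,
                  TRUE, TRUE, TRUE,
                  FALSE, TRUE, TRUE), 3, 3)
  expect_equal(max(pathfpc:::single_linkage_components(adj)), 1L)
})

test_that("pattern fixtures and replicate truth labels are coherent", {
  for (nm in c("pattern1", "pattern2", "pattern3")) {
    pat <- sim_pattern(nm)
    expect_equal(sum(pat$gene_sizes), pat$n_snps)
    expect_equal(length(pat$causal_idx), length(pat$causal_maf))
    expect_equal(length(pat$causal_err), length(pat$causal_maf))
  }
  pat1 <- sim_pattern("pattern1")
  expect_equal(pat1$n_genes, 15L)
  expect_equal(pat1$n_snps, 159L)
  expect_equal(pat1$n_assoc, 2L)
  expect_equal(length(pat1$causal_idx), 4L)
  sim <- simulate_replicate(sim_pattern("pattern1", 50, 60), f = 0.98,
                            n_cases = 50, n_controls = 60, seed = 89)
  expect_equal(sum(sim$ds$y), 50L)
  expect_equal(sum(1 - sim$ds$y), 60L)
  expect_equal(sim$truth$rr, 0.98 * pat1$causal_err)
  # every causal SNP maps to an associated gene
  gene_of <- rep(names(sim$gene_map$assignments),
                 lengths(sim$gene_map$assignments))
  expect_true(all(gene_of[sim$truth$causal_idx] %in% sim$truth$assoc_genes))
  # realized MAF close to target at the causal SNPs (3 MC SDs, n = 110)
  big <- simulate_replicate(sim_pattern("pattern1", 2000, 2000), null = TRUE,
                            n_cases = 2000, n_controls = 2000,
                            ld = list(model = "independent"), seed = 90)
  # under the null all SNPs keep their drawn U(0.05, 0.5) MAFs; check HW mean
  maf_hat <- colMeans(big$ds$dosages) / 2
  expect_true(all(maf_hat > 0.02 & maf_hat < 0.55))
  # map_snps_to_genes on simulated positions recovers the generator map
  gm <- map_snps_to_genes(sim$ds$snps, sim$genes)
  expect_equal(gm$assignments, sim$gene_map$assignments)
})
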