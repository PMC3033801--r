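# Pathway LR statistics, size-constrained permutation p-values, NLR and
# FDR/FWER across pathways.

test_that("lr_full: degenerate phenotype errors; tiny closed-form case", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(lr_full(x, rep(1, 10)), "both phenotype classes")
  # K = 1, perfectly balanced antisymmetric score: 4 samples, score
  # (-1, 1, -1, 1), y = (0, 1, 0, 1) is separated -> use a solvable variant
  # y = (0, 1, 1, 0) on score (-1, 1, -1, 1): cases and controls both have
  # mean score 0, so the MLE slope is 0 and T = 0
  s <- matrix(c(-1, 1, -1, 1))
  out <- lr_full(s, c(0, 1, 1, 0))
  expect_equal(out$T, 0, tolerance = 1e-8)
  expect_equal(out$p_chi2, 1, tolerance = 1e-6)
  # independent GLM oracle on a 1-gene model
  set.seed(61)
  x1 <- matrix(rnorm(60))
  y1 <- rbinom(60, 1, plogis(0.8 * x1))
  g0 <- glm(y1 ~ 1, family = binomial())
  g1 <- glm(y1 ~ x1, family = binomial())
  expect_equal(lr_full(x1, y1)$T,
               as.numeric(2 * (logLik(g1) - logLik(g0))), tolerance = 1e-6)
})

test_that("lr_subset: nesting monotonicity and equality with lr_full", {
  sig <- make_signal_scores(100, 4, beta = 0.8, seed = 62)
  expect_equal(lr_subset(sig$scores, sig$y), lr_full(sig$scores, sig$y)$T,
               tolerance = 1e-10)
  t1 <- lr_subset(sig$scores[, 1, drop = FALSE], sig$y)
  t12 <- lr_subset(sig$scores[, 1:2], sig$y)
  tall <- lr_subset(sig$scores, sig$y)
  expect_lte(t1, t12 + 1e-8)
  expect_lte(t12, tall + 1e-8)
})

test_that("lr_full mean statistic is ~K and null p-values are uniform", {
  set.seed(63)
  Ts <- ps <- numeric(300)
  for (i in 1:300) {
    x <- matrix(rnorm(150 * 3), 150, 3)
    y <- rep(c(0L, 1L), 75)
    out <- lr_full(x, y)
    Ts[i] <- out$T
    ps[i] <- out$p_chi2
  }
  expect_equal(mean(Ts) / 3, 1, tolerance = 0.15)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("permutation p-value: formula, determinism, add-one variant", {
  sig <- make_signal_scores(90, 3, beta = 2, seed = 64)
  res <- fpc_pathway_test(sig$scores, sig$y, "bic", B = 60, seed = 7)
  res2 <- fpc_pathway_test(sig$scores, sig$y, "bic", B = 60, seed = 7)
  expect_identical(res$p_value, res2$p_value)          # same seed, same p
  expect_identical(res$perm_stats, res2$perm_stats)
  expect_equal(res$p_value, mean(res$perm_stats > res$T))
  expect_true(res$m >= 1 && res$m <= 3)
  expect_equal(length(res$perm_stats), 60L)
  # strong signal: T beats every permutation -> literal p = 0, add-one 1/(B+1)
  if (all(res$perm_stats < res$T)) {
    expect_equal(res$p_value, 0)
    res_a <- fpc_pathway_test(sig$scores, sig$y, "bic", B = 60, seed = 7,
                              estimator = "add_one")
    expect_equal(res_a$p_value, 1 / 61)
  }
  # both criteria in one call share the permutation ensemble
  both <- fpc_pathway_test(sig$scores, sig$y, c("bic", "aic"), B = 40,
                           seed = 9)
  expect_named(both, c("bic", "aic"))
  expect_equal(both$bic$B, 40L)
})

test_that("nlr: arithmetic, affine invariance, degenerate SD", {
  out <- nlr(5, c(1, 3))
  expect_equal(out$nlr, (5 - 2) / sqrt(2), tolerance = 1e-12)
  expect_equal(out$nlr_perm, (c(1, 3) - 2) / sqrt(2))
  expect_equal(nlr(2, c(1, 2, 3))$nlr, 0)
  set.seed(65)
  ps <- rchisq(50, 3)
  a <- nlr(4, ps)
  b <- nlr(10 * 4 + 2, 10 * ps + 2)       # joint affine rescaling
  expect_equal(a$nlr, b$nlr, tolerance = 1e-12)
  expect_error(nlr(1, c(2, 2, 2)), "SD = 0")
  expect_error(nlr(1, 2), "at least 2")
})

test_that("fdr_fwer matches hand enumeration on a 3-pathway, 2-permutation table", {
  mk <- function(T, perm) list(T = T, perm_stats = perm)
  # observed NLR: (T - mean)/sd with sample SD
  # pathway A: T=10, perms (2, 4): mean 3, sd sqrt(2)  -> NLR = 4.950
  # pathway B: T=3,  perms (1, 3): mean 2, sd sqrt(2)  -> NLR = 0.707
  # pathway C: T=0,  perms (4, 6): mean 5, sd sqrt(2)  -> NLR = -3.536
  # permuted NLRs: A: (-0.707, 0.707); B: (-0.707, 0.707); C: (-0.707, 0.707)
  res <- fdr_fwer(list(A = mk(10, c(2, 4)), B = mk(3, c(1, 3)),
                       C = mk(0, c(4, 6))))
  expect_equal(res$A$NLR, 7 / sqrt(2), tolerance = 1e-12)
  # A: no permuted NLR >= 4.95 -> FDR 0, FWER 0
  expect_equal(res$A$FDR, 0)
  expect_equal(res$A$FWER, 0)
  # B: NLR = 0.707; permuted NLRs >= 0.707 occur only in permutation 2
  # (all three pathways), total 3, average per permutation 1.5; observed
  # >= 0.707: A and B -> FDR = 1.5/2 = 0.75. Per-permutation maxima are
  # (-0.707, 0.707), so only permutation 2 reaches NLR(B) -> FWER = 0.5
  expect_equal(res$B$FDR, 0.75, tolerance = 1e-12)
  expect_equal(res$B$FWER, 0.5)
  # C: NLR negative; every permuted NLR and all 3 observed exceed it ->
  # FDR = (6/2)/3 = 1 (capped), FWER = 1
  expect_equal(res$C$FDR, 1)
  expect_equal(res$C$FWER, 1)
  # literal variant pools permutation counts without dividing by B
  lit <- fdr_fwer(list(A = mk(10, c(2, 4)), B = mk(3, c(1, 3)),
                       C = mk(0, c(4, 6))), variant = "literal")
  expect_equal(lit$B$FDR, min(3 / 2, 1))
  # FWER is non-increasing in NLR
  nl <- vapply(res, `[[`, numeric(1), "NLR")
  fw <- vapply(res, `[[`, numeric(1), "FWER")
  expect_true(all(diff(fw[order(nl)]) <= 0))
  # all-equal degenerate table: total exceedance
  expect_error(fdr_fwer(list(mk(1, c(2, 2)), mk(1, c(2, 2)))), "SD = 0")
  expect_error(fdr_fwer(list(mk(1, c(1, 2)), mk(1, c(1, 2, 3)))),
               "same number of permutations")
})

test_that("global-null FWER is conservative across pathways", {
  # 20 independent null datasets x 4 disjoint 3-gene pathways: the fraction
  # of pathways with FWER <= 0.05 must stay near or below the nominal level
  seeds <- draw_seeds(40, seed = 67)
  fwers <- c()
  pc <- structure(lapply(1:4, function(i)
    list(name = paste("set", i), genes = sprintf("g%03d", (i - 1) * 3 + 1:3))),
    class = "pathway_collection")
  names(pc) <- paste0("P", 1:4)
  for (r in 1:20) {
    sim <- simulate_replicate(sim_pattern("pattern1", 80, 80), null = TRUE,
                              n_cases = 80, n_controls = 80,
                              ld = list(model = "independent"),
                              seed = seeds[r])
    res <- test_pathways(sim$ds, sim$gene_map, pc, criterion = "bic",
                         B = 100, seed = seeds[20 + r])
    fwers <- c(fwers, res$FWER)
  }
  prop <- mean(fwers <= 0.05)
  expect_lte(prop, 0.05 + 2 * sqrt(0.05 * 0.95 / length(fwers)))
})

test_that("test_pathways produces the documented results table end to end", {
  sim <- simulate_replicate(sim_pattern("pattern1", 100, 100), f = 1,
                            n_cases = 100, n_controls = 100, seed = 66)
  pc <- structure(list(
    assoc = list(name = "holds the associated genes",
                 genes = sprintf("g%03d", 1:8)),
    noise = list(name = "noise genes only",
                 genes = sprintf("g%03d", 8:15))),
    class = "pathway_collection")
  res <- test_pathways(sim$ds, sim$gene_map, pc, criterion = "bic", B = 40,
                       seed = 5)
  expect_equal(names(res), c("pathway_id", "K", "m", "T", "p_value", "NLR",
                             "FDR", "FWER", "selected_genes"))
  expect_equal(res$K, c(8L, 8L))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$FDR >= 0 & res$FDR <= 1))
  expect_true(all(res$FWER >= 0 & res$FWER <= 1))
  expect_true(all(res$T >= 0))
  expect_true(all(nchar(res$selected_genes) > 0))
})
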