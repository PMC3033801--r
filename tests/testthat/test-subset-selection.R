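# Penalized-path subset generation and AIC/BIC selection.

test_that("logistic_loglik: closed forms and brute-force agreement", {
  set.seed(41)
  y <- rbinom(40, 1, 0.4)
  x <- matrix(rnorm(80), 40, 2)
  # beta = 0 gives -n log 2
  expect_equal(logistic_loglik(x, y, c(0, 0, 0)), -40 * log(2))
  # intercept-only MLE closed form
  c1 <- sum(y)
  b0 <- qlogis(c1 / 40)
  expect_equal(logistic_loglik(x, y, c(b0, 0, 0)),
               c1 * log(c1 / 40) + (40 - c1) * log(1 - c1 / 40))
  # per-sample summation oracle
  beta <- c(0.3, -0.7, 1.1)
  expect_equal(logistic_loglik(x, y, beta),
               bernoulli_loglik_oracle(x, y, beta), tolerance = 1e-12)
})

test_that("fit_logistic matches glm and falls back under separation", {
  set.seed(42)
  x <- matrix(rnorm(200), 100, 2)
  y <- rbinom(100, 1, plogis(x[, 1]))
  f <- fit_logistic(x, y)
  g <- glm(y ~ x, family = binomial())
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-6)
  # perfectly separated data -> ridge fallback with warning
  ys <- as.integer(x[, 1] > 0)
  expect_warning(fs <- fit_logistic(x, ys), "separation")
  expect_true(fs$ridged)
  expect_true(is.finite(fs$loglik))
})

test_that("lasso_path endpoints: all genes at lambda 0, empty beyond lambda_max", {
  sig <- make_signal_scores(120, 4, beta = 0.8, seed = 43)
  path <- lasso_path(sig$scores, sig$y)
  expect_equal(path$subsets[[1]], 1:4)              # S_1 = all K genes
  expect_equal(path$lambdas[1], 0)
  expect_true(all(diff(path$lambdas) > 0))          # strictly increasing
  expect_true(all(lengths(path$subsets) >= 1))      # non-empty candidates
  # consecutive subsets distinct
  for (i in seq_along(path$subsets)[-1])
    expect_false(identical(path$subsets[[i]], path$subsets[[i - 1]]))
  # at the top of the grid the active set is empty
  L <- length(path$lambda_grid)
  expect_equal(sum(path$beta_grid[, L] != 0), 0)
  # K = 1: the path is the single all-gene subset
  p1 <- lasso_path(sig$scores[, 1, drop = FALSE], sig$y)
  expect_equal(length(p1$subsets), 1L)
  expect_equal(p1$subsets[[1]], 1L)
})

test_that("active sets along the grid match an exact coordinate-descent oracle", {
  sig <- make_signal_scores(30, 3, beta = 1.2, seed = 44)
  path <- lasso_path(sig$scores, sig$y, thresh = 1e-12)
  # compare at a spread of penalized grid points (skip lambda = 0 where the
  # active set is all genes by definition)
  idx <- unique(round(seq(2, length(path$lambda_grid), length.out = 12)))
  for (l in idx) {
    lam <- path$lambda_grid[l]
    oracle <- cd_lasso_logistic_oracle(sig$scores, sig$y, lam)
    expect_equal(unname(which(path$beta_grid[, l] != 0)), oracle,
                 info = paste("lambda =", lam))
  }
})

test_that("noise genes leave the active set before associated genes", {
  set.seed(45)
  drops_first <- 0L
  for (i in 1:200) {
    x <- matrix(rnorm(100 * 2), 100, 2,
                dimnames = list(NULL, c("signal", "noise")))
    y <- rbinom(100, 1, plogis(1.2 * x[, 1]))
    if (length(unique(y)) < 2) next
    path <- lasso_path(x, y)
    sizes <- colSums(path$beta_grid != 0)
    # last grid index (largest lambda) at which each gene is active
    last_sig <- max(which(path$beta_grid[1, ] != 0))
    last_noise <- max(which(path$beta_grid[2, ] != 0))
    if (last_sig >= last_noise) drops_first <- drops_first + 1L
  }
  expect_gte(drops_first, 190L)   # >= 95% of 200
})

test_that("AIC/BIC arithmetic and internal consistency", {
  sig <- make_signal_scores(200, 3, beta = 0.7, seed = 46)
  # arithmetic: known logL and v
  fit <- fit_logistic(sig$scores[, 1:2], sig$y, warn = FALSE)
  expect_equal(aic_score(1:2, sig$scores, sig$y), -2 * fit$loglik + 2 * 2)
  expect_equal(bic_score(1:2, sig$scores, sig$y),
               -2 * fit$loglik + log(200) * 2)
  # the two criteria differ exactly by (log n - 2) per gene (they would
  # coincide at n = e^2, which no integer sample size realizes)
  expect_equal(bic_score(1:2, sig$scores, sig$y) -
                 aic_score(1:2, sig$scores, sig$y), (log(200) - 2) * 2,
               tolerance = 1e-10)
  expect_equal(bic_score(1:3, sig$scores, sig$y) -
                 aic_score(1:3, sig$scores, sig$y), (log(200) - 2) * 3,
               tolerance = 1e-10)
  # nested subsets never lose likelihood
  ll1 <- fit_logistic(sig$scores[, 1, drop = FALSE], sig$y, warn = FALSE)$loglik
  ll12 <- fit_logistic(sig$scores[, 1:2], sig$y, warn = FALSE)$loglik
  ll123 <- fit_logistic(sig$scores, sig$y, warn = FALSE)$loglik
  expect_lte(ll1, ll12 + 1e-8)
  expect_lte(ll12, ll123 + 1e-8)
})

test_that("select_subset: minimizer, tie-breaks, and BIC within AIC sizes", {
  sig <- make_signal_scores(150, 5, beta = 1, seed = 48)
  path <- lasso_path(sig$scores, sig$y)
  sel <- select_subset(path, "aic", sig$scores, sig$y)
  scores_all <- vapply(path$subsets, aic_score, numeric(1),
                       scores = sig$scores, y = sig$y)
  expect_equal(sel$score, min(scores_all))
  # single-candidate path returns that subset
  p1 <- lasso_path(sig$scores[, 1, drop = FALSE], sig$y)
  expect_equal(select_subset(p1, "bic", sig$scores[, 1, drop = FALSE],
                             sig$y)$gene_ids, "g1")
  # property: BIC-selected size <= AIC-selected size whenever n >= 8
  set.seed(49)
  for (i in 1:60) {
    n <- sample(c(40, 80, 160), 1)
    K <- sample(3:8, 1)
    x <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, paste0("g", 1:K)))
    y <- rbinom(n, 1, plogis(0.8 * x[, 1] - 0.5 * x[, 2]))
    if (length(unique(y)) < 2) next
    p <- lasso_path(x, y)
    expect_lte(select_subset(p, "bic", x, y)$m,
               select_subset(p, "aic", x, y)$m)
  }
})

test_that("a strongly associated gene is almost always selected", {
  set.seed(50)
  hits <- 0L
  n_done <- 0L
  for (i in 1:200) {
    x <- matrix(rnorm(500 * 3), 500, 3,
                dimnames = list(NULL, c("assoc", "n1", "n2")))
    y <- rbinom(500, 1, plogis(log(3) * x[, 1]))   # OR 3 per unit score
    if (length(unique(y)) < 2) next
    n_done <- n_done + 1L
    sel <- select_subset(lasso_path(x, y), "bic", x, y)
    if ("assoc" %in% sel$gene_ids) hits <- hits + 1L
  }
  expect_gte(hits / n_done, 0.99)
})

test_that("constrained_subset: extremes, exhaustive-scan oracle, determinism", {
  sig <- make_signal_scores(80, 5, beta = 0.9, seed = 51)
  yp <- sample(sig$y)
  # m = K returns all genes under either rule
  expect_equal(constrained_subset(sig$scores, yp, 5)$idx, 1:5)
  expect_equal(constrained_subset(sig$scores, yp, 5, rule = "truncate")$idx,
               1:5)
  # truncation rule, m = 1: the last surviving gene on the path
  cs1 <- constrained_subset(sig$scores, yp, 1, rule = "truncate")
  path <- lasso_path(sig$scores, yp)
  sizes <- colSums(path$beta_grid != 0)
  last_active <- which(path$beta_grid[, max(which(sizes >= 1))] != 0)
  expect_equal(cs1$idx, unname(last_active))
  # truncation at every m agrees with a brute-force scan of the full grid
  for (m in 1:5) {
    cs <- constrained_subset(sig$scores, yp, m, rule = "truncate")
    sizes_f <- colSums(path$beta_grid != 0)
    sizes_f[path$lambda_grid == 0] <- 5
    l <- max(which(sizes_f >= m))
    act <- if (path$lambda_grid[l] == 0) 1:5
           else unname(which(path$beta_grid[, l] != 0))
    if (length(act) > m) {
      b <- abs(path$beta_grid[act, l]) * path$sd[act]
      act <- sort(act[order(-b, seq_along(act))[seq_len(m)]])
    }
    expect_equal(cs$idx, act)
    expect_equal(cs$m, m)
  }
  # criterion rule: the best-likelihood candidate of size m on the path,
  # verified against an exhaustive scan of the recorded candidates
  for (m in 1:4) {
    cs <- constrained_subset(sig$scores, yp, m)
    cand <- unique(path$subsets[lengths(path$subsets) == m])
    if (length(cand) == 0L) {
      expect_equal(cs$idx,
                   constrained_subset(sig$scores, yp, m,
                                      rule = "truncate")$idx)
    } else {
      lls <- vapply(cand, function(idx)
        fit_logistic(sig$scores[, idx, drop = FALSE], yp,
                     warn = FALSE)$loglik, numeric(1))
      expect_equal(cs$idx, cand[[which.max(lls)]])
      expect_equal(cs$m, m)
    }
  }
  # the internal permutation engine agrees with the public rule
  ll0 <- pathfpc:::intercept_loglik(yp)
  lrs <- pathfpc:::perm_constrained_lr(sig$scores, yp, 1:5, ll0)
  for (m in 1:5) {
    cs <- constrained_subset(sig$scores, yp, m)
    fit <- fit_logistic(sig$scores[, cs$idx, drop = FALSE], yp, warn = FALSE)
    expect_equal(unname(lrs[as.character(m)]),
                 max(2 * (fit$loglik - ll0), 0), tolerance = 1e-8)
  }
  # deterministic
  expect_identical(constrained_subset(sig$scores, yp, 2)$idx,
                   constrained_subset(sig$scores, yp, 2)$idx)
})
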