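# Independent oracles used across the suite. These re-derive quantities by a
# different route than the implementation (exact-objective coordinate
# descent, dense grid search, brute-force summation) and must stay free of
# the package internals they check.

# Exhaustive coordinate descent for L1-penalized logistic regression on the
# EXACT objective  -(1/n) sum[y*eta - log(1+e^eta)] + lambda * sum_j |beta_j|
# (intercept unpenalized), with predictors standardized by their 1/n SD as
# the solver under test does. Returns the active set (original indexing).
# The penalized objective is asserted non-increasing at every sweep.
cd_lasso_logistic_oracle <- function(x, y, lambda, max_sweep = 5000L,
                                     tol = 1e-9) {
  n <- nrow(x)
  sdv <- apply(x, 2L, function(v) sqrt(mean((v - mean(v))^2)))
  xs <- sweep(x, 2L, sdv, "/")
  q <- ncol(xs)
  beta0 <- 0
  beta <- numeric(q)
  obj <- function(b0, b) {
    eta <- b0 + drop(xs %*% b)
    -(mean(y * eta - log1p(exp(eta)))) + lambda * sum(abs(b))
  }
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  o_old <- obj(beta0, beta)
  for (sweep_i in seq_len(max_sweep)) {
    delta <- 0
    # intercept: 1-d Newton step on the smooth part
    eta <- beta0 + drop(xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    step <- sum(y - mu) / sum(w)
    beta0 <- beta0 + step
    delta <- max(delta, abs(step))
    for (j in seq_len(q)) {
      eta <- beta0 + drop(xs %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      g <- -mean(xs[, j] * (y - mu))
      h <- mean(w * xs[, j]^2)
      z <- h * beta[j] - g
      bj <- soft(z, lambda) / h
      delta <- max(delta, abs(bj - beta[j]))
      beta[j] <- bj
    }
    o_new <- obj(beta0, beta)
    stopifnot(o_new <= o_old + 1e-10)  # CD never increases the objective
    o_old <- o_new
    if (delta < tol) break
  }
  which(abs(beta) > 0)
}

# Dense grid search over (alpha, zeta) for the AML contamination-mixture
# log-likelihood ratio; direct evaluation, no EM.
aml_grid_oracle <- function(z, alpha_grid = seq(0, 0.6, by = 0.005),
                            zeta_grid = seq(0, 4, by = 0.02)) {
  best <- c(lambda = 0, alpha = 0, zeta = 0)
  for (zt in zeta_grid) {
    a_col <- exp(z * zt - zt^2 / 2)
    b_col <- exp(-z * zt - zt^2 / 2)
    mix <- 0.5 * (a_col + b_col)          # density ratio of the shifted part
    for (al in alpha_grid) {
      lam <- sum(log((1 - al) + al * mix))
      if (lam > best["lambda"]) best <- c(lambda = lam, alpha = al, zeta = zt)
    }
  }
  best
}

# Brute-force Bernoulli log-likelihood: per-sample summation.
bernoulli_loglik_oracle <- function(scores, y, beta) {
  tot <- 0
  for (i in seq_len(nrow(scores))) {
    eta <- beta[1] + sum(scores[i, ] * beta[-1])
    p <- 1 / (1 + exp(-eta))
    tot <- tot + if (y[i] == 1) log(p) else log(1 - p)
  }
  tot
}

# small deterministic genotype dataset used by several IO tests
make_tiny_dataset <- function() {
  dos <- matrix(c(0, 1, 2, 1,
                  2, 2, 0, 0,
                  1, 0, 1, 1), nrow = 4L)
  snps <- data.frame(snp_id = c("rs1", "rs2", "rs3"), chrom = "1",
                     pos = c(100L, 2000L, 9000L),
                     minor_allele = c("A", "C", "T"),
                     major_allele = c("G", "T", "C"),
                     stringsAsFactors = FALSE)
  genotype_dataset(dos, c(1L, 1L, 0L, 0L), snps,
                   samples = paste0("ind", 1:4))
}

# simulated scores with one truly associated gene among noise genes
make_signal_scores <- function(n, K, beta = 1, seed = NULL) {
  pathfpc:::with_seed(seed, {
    x <- matrix(stats::rnorm(n * K), n, K,
                dimnames = list(NULL, paste0("g", seq_len(K))))
    y <- stats::rbinom(n, 1L, stats::plogis(beta * x[, 1L]))
    list(scores = x, y = y)
  })
}
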