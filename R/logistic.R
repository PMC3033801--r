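# Logistic-model backbone shared by subset selection and the pathway LR
# statistics. Refits are always UNPENALIZED maximum likelihood (the criterion
# and LR definitions reference the maximized log-likelihood), with a tiny
# ridge fallback only when the ML fit is degenerate (perfect separation).

#' Bernoulli log-likelihood of a logistic model
#'
#' Log-likelihood of `y` under a logistic (logit-link Bernoulli) model with
#' linear predictor `beta[1] + scores %*% beta[-1]`. The intercept is always
#' the first element of `beta`. The linear predictor is clipped at |eta| <=
#' 35 to avoid overflow; beyond that point the likelihood is constant to
#' double precision.
#'
#' @param scores numeric matrix `n x q` of gene scores (no intercept column).
#' @param y binary 0/1 phenotype vector of length `n`.
#' @param beta numeric vector of length `q + 1`: intercept then coefficients.
#' @return scalar log-likelihood.
#' @export
logistic_loglik <- function(scores, y, beta) {
  scores <- as.matrix(scores)
  stopifnot(length(beta) == ncol(scores) + 1L, length(y) == nrow(scores))
  eta <- drop(beta[1L] + scores %*% beta[-1L])
  eta <- pmin(pmax(eta, -35), 35)
  sum(y * eta - log1p(exp(eta)))
}

# Maximized log-likelihood of the intercept-only model, in closed form.
intercept_loglik <- function(y) {
  n <- length(y)
  c1 <- sum(y)
  if (c1 == 0L || c1 == n) return(0)
  c1 * log(c1 / n) + (n - c1) * log(1 - c1 / n)
}

# IRLS logistic fit with an L2 penalty on the non-intercept coefficients.
# Used only as a stabilizer under (near-)separation; the reported
# log-likelihood is the unpenalized one at the solution.
ridge_logistic <- function(X, y, lambda = 1e-8, maxit = 200L, tol = 1e-10) {
  Xi <- cbind(1, X)
  q <- ncol(Xi)
  pen <- diag(c(0, rep(2 * lambda * length(y), q - 1L)), q)
  beta <- numeric(q)
  beta[1L] <- stats::qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(Xi %*% beta), -35), 35)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xi, y - mu)) - drop(pen %*% beta)
    H <- crossprod(Xi * w, Xi) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Newton (IRLS) maximization of the logistic log-likelihood with
# step-halving. Called hundreds of thousands of times in permutation loops,
# so it avoids glm.fit's per-call family and deviance machinery; agreement
# with stats::glm is property-tested.
irls_logistic <- function(Xi, y, maxit = 60L, tol = 1e-10) {
  beta <- numeric(ncol(Xi))
  beta[1L] <- stats::qlogis(mean(y))
  eta <- pmin(pmax(drop(Xi %*% beta), -35), 35)
  ll <- sum(y * eta - log1p(exp(eta)))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    step <- tryCatch(solve(crossprod(Xi * w, Xi), crossprod(Xi, y - mu)),
                     error = function(e) NULL)
    if (is.null(step)) break
    fac <- 1
    for (half in 1:10) {
      beta_new <- beta + fac * step
      eta_new <- pmin(pmax(drop(Xi %*% beta_new), -35), 35)
      ll_new <- sum(y * eta_new - log1p(exp(eta_new)))
      if (ll_new >= ll - 1e-12) break
      fac <- fac / 2
    }
    delta <- ll_new - ll
    beta <- beta_new
    eta <- eta_new
    ll <- ll_new
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  list(coef = drop(beta), loglik = ll, converged = converged,
       max_eta = max(abs(eta)))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Newton/IRLS fit returning the coefficient vector (intercept first) and
#' maximized log-likelihood. If the ML fit fails to converge or shows
#' perfect separation, a ridge-stabilized fit (penalty 1e-8) is substituted
#' and, when `warn = TRUE`, a warning is raised.
#'
#' @param X numeric matrix `n x q` of predictors (may have zero columns for
#'   the intercept-only model), or `NULL`.
#' @param y binary 0/1 vector.
#' @param warn warn when the ridge fallback is used.
#' @return list with `coef` (length q+1), `loglik`, `converged`, `ridged`.
#' @export
fit_logistic <- function(X, y, warn = TRUE) {
  y <- as.integer(y)
  if (is.null(X) || NCOL(X) == 0L) {
    p <- mean(y)
    b0 <- if (p <= 0 || p >= 1) sign(p - 0.5) * 35 else stats::qlogis(p)
    return(list(coef = b0, loglik = intercept_loglik(y),
                converged = TRUE, ridged = FALSE))
  }
  X <- as.matrix(X)
  Xi <- cbind(1, X)
  fit <- irls_logistic(Xi, y)
  if (!fit$converged || fit$max_eta > 30) {
    if (warn) warning("logistic ML fit degenerate (possible separation); ",
                      "using ridge-stabilized fit (penalty 1e-8)")
    beta <- ridge_logistic(X, y)
    return(list(coef = beta, loglik = logistic_loglik(X, y, beta),
                converged = TRUE, ridged = TRUE))
  }
  list(coef = unname(fit$coef), loglik = fit$loglik,
       converged = TRUE, ridged = FALSE)
}

# Likelihood-ratio statistic of a logistic model against intercept-only.
logistic_lr <- function(X, y, warn = FALSE) {
  fit <- fit_logistic(X, y, warn = warn)
  max(2 * (fit$loglik - intercept_loglik(y)), 0)
}
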