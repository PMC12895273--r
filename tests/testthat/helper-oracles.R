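# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the hypergeometric function is evaluated by its
# Euler integral representation (not the series), marginal likelihoods by
# stats::integrate (not the trapezoid grid), and the prior by dbeta.

# 2F1(a, b; c; z) via the Euler integral (requires c > b > 0, z < 1)
oracle_hyp2f1 <- function(a, b, c, z) {
  f <- function(t) t^(b - 1) * (1 - t)^(c - b - 1) * (1 - z * t)^(-a)
  exp(lgamma(c) - lgamma(b) - lgamma(c - b)) *
    stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

# exact sampling density of r given rho (unnormalized in rho), via the
# integral-representation hypergeometric
oracle_r_lik <- function(r, rho, n) {
  exp(((n - 1) / 2) * log1p(-rho^2) + ((3 - 2 * n) / 2) * log1p(-rho * r)) *
    oracle_hyp2f1(0.5, 0.5, (2 * n - 1) / 2, (1 + rho * r) / 2)
}

# stretched symmetric beta prior via dbeta
oracle_prior <- function(rho, kappa) dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2

# BF01 as a direct marginal-likelihood ratio: L(r | rho = 0) over the
# prior-weighted marginal, by adaptive quadrature
oracle_bf01 <- function(r, n, kappa = 1) {
  lik <- Vectorize(function(rho) oracle_r_lik(r, rho, n))
  marginal <- stats::integrate(function(rho) lik(rho) * oracle_prior(rho, kappa),
                               -1, 1, rel.tol = 1e-9)$value
  oracle_r_lik(r, 0, n) / marginal
}

# independent iteratively-reweighted least squares for a Gamma GLM with
# identity link (weights 1/mu^2), written without glm()
oracle_gamma_irls <- function(x, y, max_iter = 200L, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))  # OLS start
  for (i in seq_len(max_iter)) {
    mu <- drop(X %*% beta)
    W <- diag(1 / mu^2)
    beta_new <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    if (max(abs(beta_new - beta)) < tol) break
    beta <- beta_new
  }
  drop(beta)
}

# convenience: cohort config used by several tests (small but complete)
toy_cohort <- function(n = 8L, seed = 7L, ...) {
  generate_cohort(cohort_config(n, seed = seed, ...))
}
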