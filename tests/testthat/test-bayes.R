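# Bayesian correlation engine: prior, posterior, Bayes factors, indices,
# sequential design.

test_that("stretched beta prior: uniform at kappa = 1, normalized on the grid", {
  expect_equal(stretched_beta_density(c(-0.5, 0, 0.9), kappa = 1),
               rep(0.5, 3))
  for (k in c(0.25, 0.5, 1)) {
    p <- rho_posterior(0.2, n = 30, kappa = k)
    expect_equal(imcor:::trapz(p$rho, p$prior), 1, tolerance = 1e-6)
    expect_equal(imcor:::trapz(p$rho, p$posterior), 1, tolerance = 1e-6)
  }
})

test_that("posterior is symmetric under r = 0 and consistent as n grows", {
  p <- rho_posterior(0, n = 40, kappa = 1)
  idx <- posterior_indices(p)
  expect_equal(idx$median, 0, tolerance = 1e-6)
  expect_equal(idx$pd, 50, tolerance = 0.1)

  p_big <- rho_posterior(0.3, n = 10000, kappa = 1)
  idx_big <- posterior_indices(p_big)
  expect_lt(abs(idx_big$median - 0.3), 0.01)
  expect_lt(idx_big$cri[2] - idx_big$cri[1], 0.05)
})

test_that("Savage-Dickey BF: identities, direction and monotonicity", {
  bf <- bayes_factor(rho_posterior(0.4, 60))
  expect_equal(unname(bf["bf10"] * bf["bf01"]), 1, tolerance = 1e-9)

  expect_gt(bayes_factor(rho_posterior(0, 50))["bf01"], 1)
  expect_gt(bayes_factor(rho_posterior(0.9, 100))["bf10"], 100)

  # strictly increasing in |r| at fixed n, kappa
  bfs <- vapply(seq(0, 0.9, by = 0.1),
                function(r) unname(bayes_factor(rho_posterior(r, 50))["bf10"]),
                numeric(1))
  expect_true(all(diff(bfs) > 0))

  # evidence accumulates under the null as n doubles
  b1 <- bayes_factor(rho_posterior(0, 50))["bf01"]
  b2 <- bayes_factor(rho_posterior(0, 100))["bf01"]
  expect_gt(b2, b1)
})

test_that("Savage-Dickey agrees with the marginal-likelihood oracle (spot checks)", {
  cases <- list(c(0.5, 20, 1), c(-0.3, 45, 0.5), c(0.1, 120, 1 / 3))
  for (cs in cases) {
    got <- unname(bayes_factor(rho_posterior(cs[1], cs[2], cs[3]))["bf01"])
    want <- unname(oracle_bf01(cs[1], cs[2], cs[3]))
    expect_equal(got, want, tolerance = 0.005)
  }
})

test_that("posterior indices match an enumeration oracle on a toy 5-point grid", {
  rho <- c(-0.5, -0.25, 0, 0.25, 0.5)
  dens <- c(0.2, 0.6, 1.6, 1.2, 0.4)
  toy <- list(rho = rho, posterior = dens)

  # independent enumeration with literal trapezoid masses
  h <- 0.25
  w <- c(h * dens[1] / 2, h * dens[2], h * dens[3], h * dens[4], h * dens[5] / 2)
  w <- w / sum(w)
  # median sign: P(rho > 0) from the cumulative trapezoid
  cdf <- c(0, cumsum(h * (dens[-5] + dens[-1]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  p_pos <- 1 - approx(rho, cdf, xout = 0)$y
  med <- approx(cdf, rho, xout = 0.5)$y
  pd_expect <- 100 * if (med >= 0) p_pos else 1 - p_pos
  # HDI: highest-density points until mass >= 0.95 (order: 0, 0.25, -0.25, 0.5, -0.5)
  ord <- order(dens, decreasing = TRUE)
  keep <- ord[seq_len(which(cumsum(w[ord]) >= 0.95)[1])]
  rope_expect <- 100 * sum(w[keep][rho[keep] >= -0.1 & rho[keep] <= 0.1]) /
    sum(w[keep])

  idx <- posterior_indices(toy)
  expect_equal(idx$pd, pd_expect, tolerance = 1e-10)
  expect_equal(idx$rope_pct, rope_expect, tolerance = 1e-10)
  expect_equal(idx$median, med, tolerance = 1e-10)
})

test_that("a posterior concentrated inside the ROPE gives rope_pct = 100", {
  idx <- posterior_indices(rho_posterior(0, n = 5000))
  expect_equal(idx$rope_pct, 100)
  expect_true(all(abs(idx$hdi) < 0.1))
})

test_that("correlate handles degenerate, rank and error cases", {
  x <- rnorm(70)
  ci <- correlate(x, x)
  expect_equal(ci$r_obs, 1)
  expect_gt(ci$bf10, 1e6)
  expect_equal(ci$pd, 100, tolerance = 0.01)

  # monotone nonlinear relation: Spearman sees a perfect correlation
  ci_sp <- correlate(x, x^3, method = "spearman")
  expect_equal(ci_sp$r_obs, 1)

  set.seed(2)
  xn <- rnorm(1000); yn <- rnorm(1000)
  ci_null <- correlate(xn, yn)
  expect_lt(abs(ci_null$r_obs), 0.1)
  expect_gt(ci_null$bf01, 1)

  expect_error(correlate(1:5, 1:4), "equal length")
  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlate(rnorm(3), rnorm(3)), "at least 4")
})

test_that("interpretation bins follow the printed cut-points", {
  expect_equal(interpret_r(c(0.05, -0.2, 0.5, 0.8, 0.95)),
               c("negligible", "weak", "moderate", "strong", "very strong"))
  expect_equal(interpret_bf(c(1, 2, 5, 15, 50, 200)),
               c("inconclusive", "anecdotal", "moderate", "strong",
                 "very strong", "extreme"))
  expect_equal(interpret_bf(0.2), "moderate (H0)")
})

test_that("run_sequential: stopping rules, shrink schedule and oracle agreement", {
  x <- rnorm(140)
  so <- run_sequential(x, x + rnorm(140, 0, 1e-6))
  expect_equal(so$decision, "H1")
  expect_equal(so$stop_n, 70)

  # null stream: compare the whole look-by-look trace against a direct
  # re-evaluation with correlate() at each interim n
  set.seed(33)
  xs <- rnorm(140); ys <- rnorm(140)
  so0 <- run_sequential(xs, ys)
  for (i in seq_len(nrow(so0$looks))) {
    lk <- so0$looks[i, ]
    ci <- correlate(xs[1:lk$n], ys[1:lk$n], kappa = shrink_inv_sqrt(lk$look))
    expect_equal(lk$bf10, ci$bf10, tolerance = 1e-12)
  }
  last <- so0$looks[nrow(so0$looks), ]
  if (so0$decision == "H1") expect_gte(last$bf10, 10)
  if (so0$decision == "H0") expect_gte(last$bf01, 3)

  # constant shrink + a single look reduces exactly to correlate()
  set.seed(4)
  xa <- rnorm(80); ya <- 0.3 * xa + rnorm(80)
  so1 <- run_sequential(xa, ya, looks = 80L, shrink = function(k) 1)
  ci1 <- correlate(xa[1:80], ya[1:80], kappa = 1)
  expect_equal(so1$looks$bf10, ci1$bf10, tolerance = 1e-12)
  expect_equal(so1$looks$r_obs, ci1$r_obs)

  # exhaustion branch: thresholds no data can reach
  so2 <- run_sequential(xa, ya, looks = c(10L, 20L, 40L),
                        bf_h1 = 1e12, bf_h0 = 1e12)
  expect_equal(so2$decision, "inconclusive")
  expect_equal(so2$stop_n, 40L)

  expect_error(run_sequential(rnorm(50), rnorm(50)), "stream exhausted")
})
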