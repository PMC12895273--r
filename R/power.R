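# Sample-size calculations and design-level simulations: closed-form
# frequentist n, precision-based n, fixed-N Bayesian power, and operating
# characteristics of the sequential stopping design.

#' Closed-form frequentist sample size for a correlation test
#'
#' Fisher-z formula: `ceiling(((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3)`.
#'
#' @param r planning correlation, 0 < r < 1.
#' @param alpha two-tailed type-I rate.
#' @param power target power.
#' @return integer sample size.
#' @export
#' @examples
#' frequentist_n(0.3, 0.05, 0.95)  # 139
frequentist_n <- function(r, alpha = 0.05, power = 0.95) {
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  as.integer(ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) / atanh(r))^2 + 3))
}

#' Precision-based sample size for a correlation estimate
#'
#' Smallest `n` whose two-sided Fisher-z confidence interval for the
#' correlation, evaluated at the planning value `r`, has back-transformed
#' width at most `ci_width`. Different software conventions (expected width
#' vs width at `r`, approximations of the z-scale SE) shift this figure by
#' a few participants; the value is therefore reported together with the
#' convention used.
#'
#' @param r planning correlation (|r| < 1).
#' @param ci_width maximum CI width on the correlation scale, in (0, 2).
#' @param conf confidence level.
#' @param n_max search ceiling.
#' @return integer sample size with attribute `"convention"`.
#' @export
#' @examples
#' precision_n(0.3, 0.3)
precision_n <- function(r, ci_width, conf = 0.95, n_max = 1e6L) {
  stopifnot(abs(r) < 1, ci_width > 0, ci_width < 2)
  q <- qnorm(1 - (1 - conf) / 2)
  z <- atanh(r)
  width <- function(n) tanh(z + q / sqrt(n - 3)) - tanh(z - q / sqrt(n - 3))
  for (n in 4:n_max) if (width(n) <= ci_width)
    return(structure(as.integer(n),
                     convention = "two-sided Fisher-z interval evaluated at r"))
  stop("requested precision unreachable below n_max")
}

# Bayes factor (bf10) for an observed correlation; thin wrapper used by the
# simulation loops
bf_correlation <- function(r, n, kappa = 1, grid_n = 4001L) {
  unname(bayes_factor(rho_posterior(r, n, kappa = kappa, grid_n = grid_n))["bf10"])
}

#' Fixed-N Bayesian power for the correlation design
#'
#' Simulates bivariate-normal samples of size `n`, computes the Bayes
#' factor of each with prior width `kappa`, and estimates (i) the
#' probability that `bf10 > bf_h1` when the true correlation is `true_r`
#' and (ii) the probability that `bf01 > bf_h0` in a paired run under a
#' true correlation of 0 (the only coherent generating value for the
#' H0-evidence probability). Monte-Carlo standard errors accompany both.
#'
#' @param true_r generating correlation for the H1 arm.
#' @param n sample size per replicate.
#' @param reps number of replicates (>= 100).
#' @param kappa prior width used in the Bayes factor.
#' @param seed integer seed.
#' @param bf_h1,bf_h0 evidence thresholds (defaults 10 and 3).
#' @param grid_n posterior grid size.
#' @return object of class `power_result`: list with `p_bf10_gt_h1`,
#'   `p_bf01_gt_h0` (percent), their `mc_se` (percent), and the settings.
#' @export
bayesian_power <- function(true_r, n, reps = 1000L, kappa = 1, seed = 1L,
                           bf_h1 = 10, bf_h0 = 3, grid_n = 4001L) {
  if (reps < 100) stop("reps must be >= 100")
  set.seed(as.integer(seed))
  hit1 <- logical(reps)
  hit0 <- logical(reps)
  for (i in seq_len(reps)) {
    xy <- generate_bivariate(n, true_r)
    bf <- bf_correlation(cor(xy[, 1], xy[, 2]), n, kappa, grid_n)
    hit1[i] <- bf > bf_h1
    xy0 <- generate_bivariate(n, 0)
    bf0 <- bf_correlation(cor(xy0[, 1], xy0[, 2]), n, kappa, grid_n)
    hit0[i] <- (1 / bf0) > bf_h0
  }
  p1 <- 100 * mean(hit1)
  p0 <- 100 * mean(hit0)
  mc_se <- function(p) 100 * sqrt(p / 100 * (1 - p / 100) / reps)
  structure(
    list(true_r = true_r, n = as.integer(n), reps = as.integer(reps),
         kappa = kappa, bf_h1 = bf_h1, bf_h0 = bf_h0,
         p_bf10_gt_h1 = p1, p_bf01_gt_h0 = p0,
         mc_se_h1 = mc_se(p1), mc_se_h0 = mc_se(p0)),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Bayesian power (n = %d, kappa = %.3g, %d reps):\n", x$n, x$kappa, x$reps))
  cat(sprintf("  P(BF10 > %g | rho = %.2g) = %.1f%% (MC SE %.1f)\n",
              x$bf_h1, x$true_r, x$p_bf10_gt_h1, x$mc_se_h1))
  cat(sprintf("  P(BF01 > %g | rho = 0)   = %.1f%% (MC SE %.1f)\n",
              x$bf_h0, x$p_bf01_gt_h0, x$mc_se_h0))
  invisible(x)
}

#' Operating characteristics of the sequential stopping design
#'
#' Simulates full data streams and runs the sequential correlation analysis
#' on each, tallying the decision probabilities and the stopping-time
#' distribution under a given true correlation and shrinkage rule.
#'
#' @param true_r generating correlation.
#' @param reps number of simulated studies (>= 100).
#' @param looks interim sample sizes (default 70 to 140 by 10).
#' @param shrink prior-width schedule, a function of the look index
#'   (default [shrink_inv_sqrt]; use `function(k) 1` for no shrinkage).
#' @param seed integer seed.
#' @param bf_h1,bf_h0 evidence thresholds.
#' @param grid_n posterior grid size.
#' @return list with `true_r`, `p_h1`, `p_h0`, `p_inconclusive` (percent),
#'   `stop_n` (table of stopping sample sizes) and `reps`.
#' @export
sequential_operating_characteristics <- function(true_r, reps = 200L,
                                                 looks = seq(70L, 140L, 10L),
                                                 shrink = shrink_inv_sqrt,
                                                 seed = 1L,
                                                 bf_h1 = 10, bf_h0 = 3,
                                                 grid_n = 2001L) {
  if (reps < 100) stop("reps must be >= 100")
  set.seed(as.integer(seed))
  n_max <- max(looks)
  decisions <- character(reps)
  stop_ns <- integer(reps)
  for (i in seq_len(reps)) {
    xy <- generate_bivariate(n_max, true_r)
    so <- run_sequential(xy[, 1], xy[, 2], looks = looks, shrink = shrink,
                         bf_h1 = bf_h1, bf_h0 = bf_h0, grid_n = grid_n)
    decisions[i] <- so$decision
    stop_ns[i] <- so$stop_n
  }
  list(true_r = true_r, reps = as.integer(reps),
       p_h1 = 100 * mean(decisions == "H1"),
       p_h0 = 100 * mean(decisions == "H0"),
       p_inconclusive = 100 * mean(decisions == "inconclusive"),
       stop_n = table(stop_ns))
}
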