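#' Monte-Carlo power of the classical twin design to detect heritability
#'
#' Simulates replicate univariate twin cohorts under an ACE model with the
#' given generating components, fits the ACE and CE (no additive-genetic
#' variance) models by maximum likelihood, and applies the likelihood-ratio
#' test referred to the 50:50 mixture of a point mass at zero and
#' chi-square(1) -- the correct reference when the tested variance
#' component sits on the boundary of its parameter space. Power is the
#' rejection fraction with its binomial Monte-Carlo standard error.
#'
#' @param n_mz,n_dz Pairs per zygosity group.
#' @param a2,c2 Generating standardized components (`e2 = 1 - a2 - c2`).
#' @param alpha Test level.
#' @param reps Number of simulated cohorts (at least 200).
#' @param seed Integer seed.
#' @param restarts Optimizer restarts per fit (the default 1 extra start
#'   is ample for the 2-3 parameter univariate model).
#' @return A `twin_power` object: `power`, `se`, `n_reject`, `reps`,
#'   `alpha`, `critical_value`, and the design.
#' @examples
#' \donttest{
#' power_heritability(167, 208, a2 = 0.40, c2 = 0, reps = 500, seed = 1)
#' }
#' @export
power_heritability <- function(n_mz, n_dz, a2, c2 = 0, alpha = 0.05,
                               reps = 2000, seed = NULL, restarts = 1) {
  stopifnot(a2 >= 0, c2 >= 0, a2 + c2 <= 1, reps >= 200,
            alpha > 0, alpha < 0.5)
  e2 <- 1 - a2 - c2
  # mixture test: p = 0.5 P(chi2_1 >= LRT) < alpha  <=>  LRT > this
  crit <- stats::qchisq(1 - 2 * alpha, 1)
  sim_group <- function(n, r) {
    sigma <- matrix(c(1, r, r, 1), 2)
    L <- t(chol(sigma))
    t(L %*% matrix(stats::rnorm(2 * n), nrow = 2))
  }
  r_mz <- a2 + c2
  r_dz <- 0.5 * a2 + c2
  with_seed(seed, {
    lrt <- vapply(seq_len(reps), function(i) {
      mz <- sim_group(n_mz, r_mz)
      dz <- sim_group(n_dz, r_dz)
      ace <- fit_uni_groups(mz, dz, restarts = restarts)
      ce <- fit_uni_groups(mz, dz, drop = "a", restarts = restarts)
      max(0, 2 * (ce$nll - ace$nll))
    }, 0)
    n_reject <- sum(lrt > crit)
    p <- n_reject / reps
    out <- list(power = p, se = sqrt(p * (1 - p) / reps),
                n_reject = n_reject, reps = reps, alpha = alpha,
                critical_value = crit,
                design = list(n_mz = n_mz, n_dz = n_dz, a2 = a2, c2 = c2))
    class(out) <- "twin_power"
    out
  })
}

#' @export
print.twin_power <- function(x, ...) {
  cat(sprintf(
    "Power %.3f (MC SE %.3f) to detect a2 = %.2f with %d MZ + %d DZ pairs\n",
    x$power, x$se, x$design$a2, x$design$n_mz, x$design$n_dz))
  cat(sprintf("LRT vs chi2(0)/chi2(1) mixture at alpha = %.3g, %d reps\n",
              x$alpha, x$reps))
  invisible(x)
}
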