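# Twin similarity and univariate ACE maximum likelihood.
#
# The two-group (MZ/DZ) Gaussian pair likelihood is parameterized by
# loadings (a, c, e), not variances, so the implied component variances
# a^2, c^2, e^2 are nonnegative without constraints. Pair covariance:
#   diag       a^2 + c^2 + e^2
#   off-diag   a^2 + c^2        (MZ)    0.5 a^2 + c^2   (DZ)

#' Reshape a cohort into per-pair score matrices
#'
#' @param cohort Long cohort `data.frame`.
#' @param stages Stages to include (default all four).
#' @return A list with elements `MZ` and `DZ`; each an
#'   `n_pairs x (2 * length(stages))` matrix, twin 1's stages first.
#' @export
pair_matrix <- function(cohort, stages = 1:4) {
  ch <- cohort[cohort$stage %in% stages, , drop = FALSE]
  k <- length(stages)
  out <- list()
  for (z in c("MZ", "DZ")) {
    sub <- ch[ch$zygosity == z, , drop = FALSE]
    fams <- unique(sub$family_id)
    m <- matrix(NA_real_, length(fams), 2 * k,
                dimnames = list(fams, c(paste0("t1_s", stages),
                                        paste0("t2_s", stages))))
    col <- match(sub$stage, stages) + k * (sub$twin_index - 1L)
    m[cbind(match(sub$family_id, fams), col)] <- sub$score
    out[[z]] <- m
  }
  out
}

#' One-way random-effects intraclass correlation for twin pairs
#'
#' The classical twin ICC: from a one-way ANOVA on pairs of size two,
#' `(MSB - MSW) / (MSB + MSW)`. Pairs with either member missing are
#' excluded. The p-value is from the one-sided F test of MSB/MSW.
#'
#' @param cohort Long cohort `data.frame`.
#' @param stage Stage at which to compute the correlations.
#' @return An `icc_estimate`: `r_mz`, `r_dz`, pair counts and p-values.
#' @export
intraclass_correlation <- function(cohort, stage) {
  pm <- pair_matrix(cohort, stages = stage)
  one <- function(x) {
    x <- x[stats::complete.cases(x), , drop = FALSE]
    n <- nrow(x)
    if (n < 2) stop("need at least 2 complete pairs")
    pair_mean <- rowMeans(x)
    msb <- 2 * stats::var(pair_mean)
    msw <- sum((x - pair_mean)^2) / n
    icc <- (msb - msw) / (msb + msw)
    p <- stats::pf(msb / msw, n - 1, n, lower.tail = FALSE)
    list(icc = icc, n = n, p = p, degenerate = msb <= msw)
  }
  mz <- one(pm$MZ)
  dz <- one(pm$DZ)
  out <- list(r_mz = mz$icc, r_dz = dz$icc,
              n_mz_pairs = mz$n, n_dz_pairs = dz$n,
              p_mz = mz$p, p_dz = dz$p,
              degenerate = c(MZ = mz$degenerate, DZ = dz$degenerate))
  class(out) <- "icc_estimate"
  out
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("MZ ICC %.3f (N = %d pairs, p = %.3g)\n",
              x$r_mz, x$n_mz_pairs, x$p_mz))
  cat(sprintf("DZ ICC %.3f (N = %d pairs, p = %.3g)\n",
              x$r_dz, x$n_dz_pairs, x$p_dz))
  invisible(x)
}

#' Falconer moment estimates of the ACE components
#'
#' The textbook formulas from the twin correlations: heritability
#' `a2 = 2 (r_mz - r_dz)`; shared environment `c2 = r_mz - a2 =
#' 2 r_dz - r_mz`; non-shared environment `e2 = 1 - r_mz`. The identity
#' `a2 + c2 + e2 = 1` holds exactly for any inputs. Estimates outside
#' \[0, 1\] are returned as computed and flagged, never silently clamped;
#' `truncated = TRUE` additionally returns a clamped-and-renormalized
#' variant.
#'
#' @param r_mz,r_dz Twin intraclass correlations in \[-1, 1\].
#' @param truncated Also compute the clamped variant.
#' @return A `falconer_estimate`: `a2`, `c2`, `e2`, `out_of_bounds` flag,
#'   and optionally `truncated`.
#' @examples
#' falconer_estimates(0.55, 0.32)  # a2 = 0.46, c2 = 0.09, e2 = 0.45
#' @export
falconer_estimates <- function(r_mz, r_dz, truncated = FALSE) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  a2 <- 2 * (r_mz - r_dz)
  c2 <- 2 * r_dz - r_mz
  e2 <- 1 - r_mz
  out <- list(a2 = a2, c2 = c2, e2 = e2,
              out_of_bounds = any(c(a2, c2, e2) < 0 | c(a2, c2, e2) > 1))
  if (truncated) {
    tr <- pmin(pmax(c(a2, c2, e2), 0), 1)
    tr <- tr / sum(tr)
    out$truncated <- list(a2 = tr[1], c2 = tr[2], e2 = tr[3])
  }
  class(out) <- "falconer_estimate"
  out
}

#' @export
print.falconer_estimate <- function(x, ...) {
  cat(sprintf("Falconer estimates: a2 = %.3f, c2 = %.3f, e2 = %.3f%s\n",
              x$a2, x$c2, x$e2,
              if (x$out_of_bounds) "  [outside [0,1]]" else ""))
  invisible(x)
}

# --- internal univariate two-group likelihood ------------------------------

# Sufficient statistics for one zygosity group: complete pairs only.
# The MLE of the (single, shared) group mean under an exchangeable 2x2
# covariance is the plain mean of all scores, independent of the
# covariance, so the mean profiles out exactly.
uni_suffstats <- function(x) {
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  mu <- mean(x)
  d <- x - mu
  list(n = n, mu = mu, T = crossprod(d) / n)
}

# 0.5 * -2 log L for both groups, par = loadings; drop picks the submodel.
uni_nll <- function(par, st_mz, st_dz, drop = character()) {
  full <- c(a = 0, c = 0, e = 0)
  full[setdiff(names(full), drop)] <- par
  v <- sum(full^2)
  if (v <= 0 || !is.finite(v)) return(1e10)
  term <- function(st, cv) {
    det <- v^2 - cv^2
    if (det <= 0) return(NA_real_)
    # tr(Sigma^-1 T) for Sigma = [[v, cv], [cv, v]]
    tr <- (v * (st$T[1, 1] + st$T[2, 2]) - 2 * cv * st$T[1, 2]) / det
    st$n * (2 * log(2 * pi) + log(det) + tr)
  }
  r <- term(st_mz, full["a"]^2 + full["c"]^2) +
       term(st_dz, 0.5 * full["a"]^2 + full["c"]^2)
  if (!is.finite(r)) return(1e10)
  0.5 * r
}

# Deterministic multi-start ML over loadings for the two-group model.
fit_uni_groups <- function(mz, dz, drop = character(), restarts = 5) {
  st_mz <- uni_suffstats(mz)
  st_dz <- uni_suffstats(dz)
  vhat <- (st_mz$n * (st_mz$T[1, 1] + st_mz$T[2, 2]) +
           st_dz$n * (st_dz$T[1, 1] + st_dz$T[2, 2])) /
          (2 * (st_mz$n + st_dz$n))
  r_mz <- st_mz$T[1, 2] / sqrt(st_mz$T[1, 1] * st_mz$T[2, 2])
  r_dz <- st_dz$T[1, 2] / sqrt(st_dz$T[1, 1] * st_dz$T[2, 2])
  fal <- falconer_estimates(max(min(r_mz, 1), -1), max(min(r_dz, 1), -1))
  props <- pmax(c(fal$a2, fal$c2, fal$e2), 0.02)
  props <- props / sum(props)
  base <- sqrt(props * vhat)
  names(base) <- c("a", "c", "e")
  keep <- setdiff(c("a", "c", "e"), drop)
  # fixed jitter grid keeps the fit deterministic without consuming RNG
  jit <- rbind(1, 0.5, 1.5,
               matrix(c(0.2, 1, 1.3, 1.3, 0.2, 1, 1, 1.3, 0.6,
                        0.7, 0.7, 1.4, 1.4, 1.4, 0.7), ncol = 3,
                      byrow = TRUE))
  best <- NULL
  for (i in seq_len(min(restarts + 1, nrow(jit)))) {
    start <- base[keep] * jit[i, seq_along(keep)]
    opt <- stats::optim(start, uni_nll, st_mz = st_mz, st_dz = st_dz,
                        drop = drop, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(par = abs(best$par), nll = best$value,
       convergence = best$convergence == 0,
       st_mz = st_mz, st_dz = st_dz, drop = drop)
}

#' Maximum-likelihood univariate ACE model at one stage
#'
#' Fits the classical two-group twin model to the complete pairs of one
#' stage by maximizing the Gaussian pair likelihood over the loadings
#' (a, c, e), with the group means profiled out exactly. Multiple
#' deterministic restarts guard against local optima.
#'
#' @param cohort Long cohort `data.frame` (scores already preprocessed).
#' @param stage Stage to fit.
#' @param min_pairs Minimum complete pairs required per zygosity group.
#' @param restarts Extra optimizer starts beyond the moment-based one.
#' @return An `ace_fit`: `params` (1-stage [ace_loadings]),
#'   `components` (standardized proportions), `loglik`,
#'   `n_free_parameters`, `convergence`, pair counts, and the internal
#'   objective for profile-likelihood intervals.
#' @export
fit_univariate_ace <- function(cohort, stage, min_pairs = 20, restarts = 5) {
  pm <- pair_matrix(cohort, stages = stage)
  n_mz <- sum(stats::complete.cases(pm$MZ))
  n_dz <- sum(stats::complete.cases(pm$DZ))
  if (n_mz < min_pairs || n_dz < min_pairs) {
    stop("need at least ", min_pairs, " complete pairs per zygosity group (",
         n_mz, " MZ, ", n_dz, " DZ available)")
  }
  f <- fit_uni_groups(pm$MZ, pm$DZ, restarts = restarts)
  par <- f$par
  params <- ace_loadings(matrix(par["a"]), matrix(par["c"]),
                         matrix(par["e"]))
  nllfun <- function(p) uni_nll(p, f$st_mz, f$st_dz)
  out <- list(params = params,
              components = standardize_components(params),
              loglik = -f$nll,
              n_free_parameters = 5L,  # a, c, e + one mean per group
              convergence = f$convergence,
              n_mz_pairs = n_mz, n_dz_pairs = n_dz,
              means = c(MZ = f$st_mz$mu, DZ = f$st_dz$mu),
              nll = nllfun, par_hat = par, stage = stage)
  class(out) <- c("uni_ace_fit", "ace_fit")
  out
}

#' @export
print.uni_ace_fit <- function(x, ...) {
  pr <- c(x$components$A[1, 1], x$components$C[1, 1], x$components$E[1, 1])
  cat(sprintf("Univariate ACE fit (stage %s): A = %.3f, C = %.3f, E = %.3f\n",
              x$stage, pr[1], pr[2], pr[3]))
  cat(sprintf("logLik %.3f, %d MZ / %d DZ complete pairs\n",
              x$loglik, x$n_mz_pairs, x$n_dz_pairs))
  invisible(x)
}

# --- profile-likelihood intervals ------------------------------------------

# Penalized profile of nll subject to qfun(par) = q (escalating quadratic
# penalty, warm-started).
profile_point <- function(nll, qfun, q, start) {
  par <- start
  val <- NA_real_
  for (rho in c(1e3, 1e5, 1e7)) {
    obj <- function(p) nll(p) + rho * (qfun(p) - q)^2
    opt <- stats::optim(par, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    par <- opt$par
    val <- nll(par)
  }
  list(nll = val, par = par)
}

# One-dimensional profile-likelihood bound search by bisection.
profile_bound <- function(nll, qfun, par_hat, q_hat, target, side,
                          limit, tol = 1e-4) {
  at_limit <- profile_point(nll, qfun, limit, par_hat)
  if (at_limit$nll <= target) {
    return(list(bound = limit, clamped = TRUE))
  }
  lo <- q_hat
  hi <- limit
  start <- par_hat
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    pp <- profile_point(nll, qfun, mid, start)
    start <- pp$par
    if (pp$nll <= target) lo <- mid else hi <- mid
    if (abs(hi - lo) < tol) break
  }
  list(bound = (lo + hi) / 2, clamped = FALSE)
}

#' Profile-likelihood confidence interval for a standardized quantity
#'
#' Bounds are where twice the drop from the maximized log-likelihood
#' equals the chi-square(1) critical value; bounds that run into the
#' admissible range \[0, 1\] of a standardized proportion are clamped
#' there (reported as .00 / 1.00), the usual boundary pattern for
#' variance components.
#'
#' @param fit An `ace_fit` from [fit_univariate_ace()] or
#'   [fit_cholesky_ace()].
#' @param quantity For univariate fits one of `"a2"`, `"c2"`, `"e2"`; for
#'   Cholesky fits a list `list(source =, stage =, factor =)` or
#'   `list(source =, stage =, total = TRUE)`.
#' @param level Confidence level (default 0.95).
#' @return A list with `lower`, `upper`, `estimate`, and `clamped` flags.
#' @export
likelihood_ci <- function(fit, quantity, level = 0.95) {
  stopifnot(inherits(fit, "ace_fit"))
  qfun <- make_qfun(fit, quantity)
  q_hat <- qfun(fit$par_hat)
  nll_min <- -fit$loglik
  target <- nll_min + stats::qchisq(level, 1) / 2
  lo <- profile_bound(fit$nll, qfun, fit$par_hat, q_hat, target,
                      side = "lower", limit = 0)
  hi <- profile_bound(fit$nll, qfun, fit$par_hat, q_hat, target,
                      side = "upper", limit = 1)
  list(lower = min(lo$bound, q_hat), upper = max(hi$bound, q_hat),
       estimate = q_hat,
       clamped = c(lower = lo$clamped, upper = hi$clamped))
}

# Map a quantity request to a function of the parameter vector.
make_qfun <- function(fit, quantity) {
  if (inherits(fit, "uni_ace_fit")) {
    quantity <- match.arg(quantity, c("a2", "c2", "e2"))
    i <- match(quantity, c("a2", "c2", "e2"))
    function(par) par[i]^2 / sum(par^2)
  } else {
    src <- match.arg(quantity$source, c("A", "C", "E"))
    stage <- quantity$stage
    rebuild <- fit$par_to_params
    if (isTRUE(quantity$total)) {
      function(par) {
        p <- rebuild(par)
        standardize_components(p)$totals[stage, src]
      }
    } else {
      fct <- quantity$factor
      function(par) {
        p <- rebuild(par)
        standardize_components(p)[[src]][stage, fct]
      }
    }
  }
}
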