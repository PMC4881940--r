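# Multivariate (longitudinal) Cholesky ACE maximum likelihood.
#
# The model: stacked stage scores of a twin pair are jointly Gaussian with
# the covariance of theoretical_pair_covariance(), parameterized by the
# three lower-triangular loading matrices. Estimation maximizes the
# two-group likelihood over all loadings. Two missing-data modes:
#   "complete"  complete pairs only; the per-group stage means are the
#               GLS/ML means and profile out of the likelihood exactly
#               (the twin-exchangeable covariance has the constant vector
#               as an eigendirection), so only the loadings are optimized.
#   "fiml"      full-information likelihood on each pair's observed
#               sub-vector, pairs grouped by missingness pattern with
#               sufficient statistics per pattern; per-group stage means
#               are free parameters.

tri_index <- function(d) which(lower.tri(diag(d), diag = TRUE))

par_to_loadings <- function(par, d) {
  k <- d * (d + 1) / 2
  idx <- tri_index(d)
  mk <- function(v) {
    m <- matrix(0, d, d)
    m[idx] <- v
    m
  }
  ace_loadings(mk(par[1:k]), mk(par[k + 1:k]), mk(par[2 * k + 1:k]))
}

loadings_to_par <- function(params) {
  idx <- tri_index(params$n_stages)
  c(params$lambda_a[idx], params$lambda_c[idx], params$lambda_e[idx])
}

# Pattern-grouped sufficient statistics for one zygosity group.
# Each pattern: observed column set, count, sum vector, raw scatter.
pattern_stats <- function(x, complete_only = FALSE) {
  obs <- !is.na(x)
  if (complete_only) {
    keep <- rowSums(obs) == ncol(x)
  } else {
    keep <- rowSums(obs) > 0
  }
  x <- x[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  out <- lapply(split(seq_len(nrow(x)), key), function(rows) {
    o <- which(obs[rows[1], ])
    xo <- x[rows, o, drop = FALSE]
    list(obs = o, n = length(rows), s = colSums(xo), M = crossprod(xo))
  })
  unname(out)
}

# 0.5 * -2 log L over both groups. `means` is a list of per-group stage
# means used when they are not part of `par`.
chol_nll <- function(par, d, stats_by_group, means = NULL) {
  k3 <- 3 * d * (d + 1) / 2
  params <- tryCatch(par_to_loadings(par[1:k3], d), error = function(e) NULL)
  if (is.null(params)) return(1e10)
  A <- tcrossprod(params$lambda_a)
  C <- tcrossprod(params$lambda_c)
  E <- tcrossprod(params$lambda_e)
  W <- A + C + E
  total <- 0
  for (g in seq_along(stats_by_group)) {
    grp <- stats_by_group[[g]]
    r_a <- if (names(stats_by_group)[g] == "MZ") 1 else 0.5
    X <- r_a * A + C
    sigma <- rbind(cbind(W, X), cbind(X, W))
    mu <- if (is.null(means)) par[k3 + (g - 1) * d + 1:d] else means[[g]]
    mu8 <- rep(mu, 2)
    for (p in grp) {
      so <- sigma[p$obs, p$obs, drop = FALSE]
      R <- tryCatch(chol(so), error = function(e) NULL)
      if (is.null(R)) return(1e10)
      sinv <- chol2inv(R)
      muo <- mu8[p$obs]
      Tp <- p$M - outer(p$s, muo) - outer(muo, p$s) + p$n * outer(muo, muo)
      total <- total + p$n * (length(p$obs) * log(2 * pi) +
                              2 * sum(log(diag(R)))) + sum(sinv * Tp)
    }
  }
  if (!is.finite(total)) return(1e10)
  0.5 * total
}

# Moment-based starting loadings from (possibly incomplete) pair matrices.
start_loadings_from_moments <- function(pm, d) {
  covs <- lapply(pm, function(x) {
    cv <- suppressWarnings(stats::cov(x, use = "pairwise.complete.obs"))
    cv[!is.finite(cv)] <- 0
    cv
  })
  n <- vapply(pm, function(x) sum(rowSums(!is.na(x)) > 0), 0)
  blocks <- lapply(covs, function(cv) {
    list(W = (cv[1:d, 1:d] + cv[d + 1:d, d + 1:d]) / 2,
         X = (cv[1:d, d + 1:d] + cv[d + 1:d, 1:d]) / 2)
  })
  W <- (n[["MZ"]] * blocks$MZ$W + n[["DZ"]] * blocks$DZ$W) / sum(n)
  A0 <- 2 * (blocks$MZ$X - blocks$DZ$X)
  C0 <- 2 * blocks$DZ$X - blocks$MZ$X
  E0 <- W - A0 - C0
  ace_loadings(psd_lower_chol(A0, 1e-4), psd_lower_chol(C0, 1e-4),
               psd_lower_chol(E0, 1e-4))
}

# Flip loading-column signs so every diagonal is nonnegative (the model is
# invariant to column sign; this picks the conventional representative).
fix_loading_signs <- function(params) {
  fix <- function(m) {
    for (j in seq_len(ncol(m))) if (m[j, j] < 0) m[, j] <- -m[, j]
    m
  }
  ace_loadings(fix(params$lambda_a), fix(params$lambda_c),
               fix(params$lambda_e))
}

#' Maximum-likelihood multivariate Cholesky ACE model
#'
#' Fits the triangular factor decomposition of the A, C and E covariance
#' across the assessment stages by maximizing the two-group (MZ/DZ)
#' Gaussian pair likelihood over all lower-triangular loadings
#' (`3 * d * (d + 1) / 2` of them for `d` stages; 30 for the four-stage
#' model). This separates variance transmitted from earlier stages
#' (factor 1 loadings on later stages) from innovations newly arising at
#' each stage (the diagonal loadings), the quantity of interest when an
#' intervention sits between assessments.
#'
#' @param cohort Long cohort `data.frame` (scores already preprocessed).
#' @param stages Stages to model jointly (default all four).
#' @param mode `"fiml"` (default) uses every pair's observed sub-vector;
#'   `"complete"` uses complete pairs only and profiles the stage means
#'   out exactly.
#' @param min_pairs Minimum usable pairs per zygosity group.
#' @param restarts Extra optimizer starts beyond the moment-based one.
#' @param control Passed to [stats::optim()] (BFGS); defaults to
#'   `reltol = 1e-12`, `maxit = 2000`.
#' @return A `cholesky_ace_fit`: `params` (fitted [ace_loadings], column
#'   signs normalized), `components` (standardized
#'   variance-components table), `loglik`, `n_free_parameters`,
#'   `convergence`, pair counts, per-group `means`, and the internal
#'   objective for profile-likelihood intervals.
#' @export
fit_cholesky_ace <- function(cohort, stages = 1:4,
                             mode = c("fiml", "complete"),
                             min_pairs = 20, restarts = 5,
                             control = list()) {
  mode <- match.arg(mode)
  d <- length(stages)
  pm <- pair_matrix(cohort, stages = stages)
  for (z in names(pm)) {
    v <- apply(pm[[z]], 2, stats::var, na.rm = TRUE)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("rank-deficient data: a stage has zero variance in the ",
           z, " group")
    }
  }
  stats_by_group <- lapply(pm, pattern_stats,
                           complete_only = (mode == "complete"))
  n_used <- vapply(stats_by_group, function(g) sum(vapply(g, `[[`, 0, "n")), 0)
  if (any(n_used < min_pairs)) {
    stop("need at least ", min_pairs, " usable pairs per zygosity group")
  }
  k3 <- 3 * d * (d + 1) / 2
  means <- NULL
  if (mode == "complete") {
    means <- lapply(pm, function(x) {
      x <- x[stats::complete.cases(x), , drop = FALSE]
      colMeans((x[, 1:d, drop = FALSE] + x[, d + 1:d, drop = FALSE]) / 2)
    })
  }
  start <- start_loadings_from_moments(pm, d)
  base_par <- loadings_to_par(start)
  if (mode == "fiml") {
    mu0 <- lapply(pm, function(x) {
      m <- colMeans(rbind(x[, 1:d, drop = FALSE],
                          x[, d + 1:d, drop = FALSE]), na.rm = TRUE)
      ifelse(is.finite(m), m, 0)
    })
    base_par <- c(base_par, mu0$MZ, mu0$DZ)
  }
  ctrl <- utils::modifyList(list(maxit = 2000, reltol = 1e-12), control)
  scout_ctrl <- utils::modifyList(ctrl, list(maxit = 150, reltol = 1e-8))
  scales <- c(1, 0.7, 1.3, 0.5, 1.5, 0.9, 1.1)
  # cheap scouting pass per start, then one full-tolerance polish of the best
  best <- NULL
  for (i in seq_len(min(restarts + 1, length(scales)))) {
    p0 <- base_par
    p0[1:k3] <- p0[1:k3] * scales[i]
    opt <- stats::optim(p0, chol_nll, d = d, stats_by_group = stats_by_group,
                        means = means, method = "BFGS", control = scout_ctrl)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  best <- stats::optim(best$par, chol_nll, d = d,
                       stats_by_group = stats_by_group, means = means,
                       method = "BFGS", control = ctrl)
  par_hat <- best$par
  params <- fix_loading_signs(par_to_loadings(par_hat[1:k3], d))
  par_hat[1:k3] <- loadings_to_par(params)
  fitted_means <- if (mode == "complete") means else
    list(MZ = par_hat[k3 + 1:d], DZ = par_hat[k3 + d + 1:d])
  nllfun <- function(p) chol_nll(p, d, stats_by_group, means)
  out <- list(params = params,
              components = standardize_components(params),
              loglik = -best$value,
              n_free_parameters = as.integer(k3 + 2 * d),
              convergence = best$convergence == 0,
              mode = mode, stages = stages,
              n_mz_pairs = n_used[["MZ"]], n_dz_pairs = n_used[["DZ"]],
              means = fitted_means,
              nll = nllfun, par_hat = par_hat,
              par_to_params = function(p) par_to_loadings(p[1:k3], d))
  class(out) <- c("cholesky_ace_fit", "ace_fit")
  out
}

#' @export
print.cholesky_ace_fit <- function(x, ...) {
  cat(sprintf("Cholesky ACE fit, %d stages (%s mode): logLik %.3f\n",
              length(x$stages), x$mode, x$loglik))
  cat(sprintf("%d MZ / %d DZ pairs, %d free parameters, converged: %s\n",
              x$n_mz_pairs, x$n_dz_pairs, x$n_free_parameters,
              x$convergence))
  print(x$components)
  invisible(x)
}

#' Tables of standardized contributions with profile-likelihood CIs
#'
#' Formats a fitted model's standardized variance-components table in the
#' conventional published layout (stage columns, factor rows, entries like
#' `"0.48 (.20-.64)"`). Confidence intervals are profile-likelihood
#' intervals and are expensive for the multivariate model, so they are
#' opt-in via `ci`.
#'
#' @param fit A `cholesky_ace_fit`.
#' @param ci `"none"` (default), `"totals"` (CIs for the per-stage A/C/E
#'   totals only) or `"all"`.
#' @param level Confidence level.
#' @return A `data.frame` with one row per factor/total and one column per
#'   stage.
#' @export
components_table <- function(fit, ci = c("none", "totals", "all"),
                             level = 0.95) {
  ci <- match.arg(ci)
  comp <- fit$components
  d <- length(fit$stages)
  rows <- list()
  for (src in c("A", "C", "E")) {
    m <- comp[[src]]
    for (j in seq_len(d)) {
      cells <- rep("", d)
      for (i in j:d) {
        if (ci == "all") {
          b <- likelihood_ci(fit, list(source = src, stage = i, factor = j),
                             level = level)
          cells[i] <- fmt_est_ci(m[i, j], b$lower, b$upper)
        } else {
          cells[i] <- sprintf("%.2f", m[i, j])
        }
      }
      rows[[paste0(src, j)]] <- cells
    }
    tot <- comp$totals[, src]
    cells <- character(d)
    for (i in seq_len(d)) {
      if (ci %in% c("totals", "all")) {
        b <- likelihood_ci(fit, list(source = src, stage = i, total = TRUE),
                           level = level)
        cells[i] <- fmt_est_ci(tot[i], b$lower, b$upper)
      } else {
        cells[i] <- sprintf("%.2f", tot[i])
      }
    }
    rows[[paste0(src, "_total")]] <- cells
  }
  out <- data.frame(parameter = names(rows),
                    do.call(rbind, rows),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[-1] <- paste0("stage", fit$stages)
  out
}
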