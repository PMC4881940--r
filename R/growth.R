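#' Piecewise time coding for the four-stage design
#'
#' Occasion coding for the growth models: `time` counts occasions from
#' baseline (0, 1, 2, 3) and carries the overall linear slope; `time2`
#' starts accumulating only when the intervention begins (0, 0, 1, 2) and
#' carries the additional post-intervention slope, so a flat control period
#' followed by improvement appears as `gamma_10` near 0 with positive
#' `gamma_20`.
#'
#' @param stages Integer vector with values in 1..4.
#' @return A `data.frame` with columns `stage`, `time`, `time2`.
#' @export
build_time_codes <- function(stages) {
  stages <- as.integer(stages)
  if (any(is.na(stages)) || any(stages < 1 | stages > 4)) {
    stop("stages must be integers in 1..4")
  }
  data.frame(stage = stages, time = stages - 1L,
             time2 = pmax(stages - 2L, 0L))
}

#' Multilevel growth model for the mean intervention response
#'
#' Fits, by full maximum likelihood, a three-level growth model for
#' repeated measures nested in individuals nested in twin pairs: fixed
#' effects `gamma_00 + gamma_10 * time` (unconditional) or
#' `... + gamma_20 * time2` (piecewise), a random intercept at the pair
#' level, random intercept and slope(s) at the individual level, and iid
#' residuals. ML (not REML) is used so likelihood-ratio comparisons of the
#' two models are valid. t statistics use residual degrees of freedom
#' `n_observations - n_fixed_effects`.
#'
#' @param data Long `data.frame` with columns `family_id`, `twin_index`,
#'   `stage` and `score` (rows with missing scores are dropped).
#' @param model `"piecewise"` (default) or `"unconditional"`.
#' @return A `growth_fit`: fixed effects (`gamma_00`, `gamma_10`,
#'   `gamma_20`), standard errors and t statistics, random-effect
#'   variances, `residual_variance`, `loglik`, `AIC`, `BIC`,
#'   `n_observations`, `n_parameters`, `singular` flag, and the underlying
#'   `lme4` fit in `$model`.
#' @export
fit_growth <- function(data, model = c("piecewise", "unconditional")) {
  model <- match.arg(model)
  df <- data[!is.na(data$score), , drop = FALSE]
  df$individual <- paste(df$family_id, df$twin_index, sep = "_")
  if (length(unique(df$individual)) < 50) {
    stop("need at least 50 individuals with observations")
  }
  tc <- build_time_codes(1:4)
  df$time <- tc$time[df$stage]
  df$time2 <- tc$time2[df$stage]
  form <- if (model == "piecewise") {
    score ~ time + time2 + (1 | family_id) + (1 + time + time2 | individual)
  } else {
    score ~ time + (1 | family_id) + (1 + time | individual)
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- suppressMessages(lme4::lmer(form, data = df, REML = FALSE,
                                     control = ctrl))
  # second optimizer guards against convergence to a poorer optimum, which
  # would otherwise break the nesting of the two models
  alt <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(form, data = df, REML = FALSE,
               control = lme4::lmerControl(optimizer = "Nelder_Mead",
                                           calc.derivs = FALSE,
                                           check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (!is.null(alt) &&
      as.numeric(stats::logLik(alt)) > as.numeric(stats::logLik(fit))) {
    fit <- alt
  }
  co <- summary(fit)$coefficients
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  gam <- function(nm) if (nm %in% rownames(co)) co[nm, "Estimate"] else 0
  se <- function(nm) if (nm %in% rownames(co)) co[nm, "Std. Error"] else NA
  n_fixed <- nrow(co)
  vc <- lme4::VarCorr(fit)
  out <- list(
    model = model,
    gamma_00 = gam("(Intercept)"), gamma_10 = gam("time"),
    gamma_20 = gam("time2"),
    se_00 = se("(Intercept)"), se_10 = se("time"), se_20 = se("time2"),
    random_effects = vc,
    residual_variance = stats::sigma(fit)^2,
    loglik = ll,
    AIC = -2 * ll + 2 * k,
    BIC = -2 * ll + k * log(n),
    n_observations = n, n_parameters = k,
    df_residual = n - n_fixed,
    singular = lme4::isSingular(fit),
    fit = fit)
  out$t_10 <- out$gamma_10 / out$se_10
  out$p_10 <- 2 * stats::pt(abs(out$t_10), out$df_residual,
                            lower.tail = FALSE)
  if (model == "piecewise") {
    out$t_20 <- out$gamma_20 / out$se_20
    out$p_20 <- 2 * stats::pt(abs(out$t_20), out$df_residual,
                              lower.tail = FALSE)
  }
  class(out) <- "growth_fit"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s growth model: logLik %.2f, AIC %.1f, BIC %.1f (n = %d)\n",
              x$model, x$loglik, x$AIC, x$BIC, x$n_observations))
  cat(sprintf("  gamma_00 = %.4f (SE %.4f)\n", x$gamma_00, x$se_00))
  cat(sprintf("  gamma_10 = %.4f (SE %.4f), t(%d) = %.2f, p = %.3g\n",
              x$gamma_10, x$se_10, x$df_residual, x$t_10, x$p_10))
  if (x$model == "piecewise") {
    cat(sprintf("  gamma_20 = %.4f (SE %.4f), t(%d) = %.2f, p = %.3g\n",
                x$gamma_20, x$se_20, x$df_residual, x$t_20, x$p_20))
  }
  invisible(x)
}

#' Compare two growth-model fits
#'
#' Reports the log-likelihood difference, the likelihood-ratio statistic
#' and degrees of freedom for nested fits (with the usual chi-square
#' p-value), AIC and BIC differences, and the preferred model under each
#' criterion.
#'
#' @param fit_a,fit_b `growth_fit` objects on identical data (`fit_b`
#'   should be the richer model when nested).
#' @return A `growth_comparison` list.
#' @export
compare_growth_models <- function(fit_a, fit_b) {
  if (fit_a$n_observations != fit_b$n_observations) {
    stop("fits use different numbers of observations")
  }
  nested <- fit_a$n_parameters != fit_b$n_parameters
  if (fit_a$n_parameters > fit_b$n_parameters) {
    tmp <- fit_a; fit_a <- fit_b; fit_b <- tmp
  }
  d_ll <- fit_b$loglik - fit_a$loglik
  df <- fit_b$n_parameters - fit_a$n_parameters
  lrt <- 2 * d_ll
  out <- list(
    delta_loglik = d_ll,
    lrt = if (nested) lrt else NA_real_,
    lrt_df = if (nested) df else NA_integer_,
    lrt_p = if (nested) stats::pchisq(max(lrt, 0), df, lower.tail = FALSE)
            else NA_real_,
    delta_AIC = fit_b$AIC - fit_a$AIC,
    delta_BIC = fit_b$BIC - fit_a$BIC,
    preferred = c(
      loglik = if (d_ll == 0) "tie" else fit_b$model,
      AIC = if (fit_b$AIC == fit_a$AIC) "tie"
            else if (fit_b$AIC < fit_a$AIC) fit_b$model else fit_a$model,
      BIC = if (fit_b$BIC == fit_a$BIC) "tie"
            else if (fit_b$BIC < fit_a$BIC) fit_b$model else fit_a$model),
    models = c(fit_a$model, fit_b$model))
  class(out) <- "growth_comparison"
  out
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: delta logLik %.3f", x$models[1], x$models[2],
              x$delta_loglik))
  if (!is.na(x$lrt)) {
    cat(sprintf(", LRT %.2f on %d df (p = %.3g)", x$lrt, x$lrt_df, x$lrt_p))
  }
  cat(sprintf("\ndelta AIC %.2f, delta BIC %.2f; preferred: %s (AIC), %s (BIC)\n",
              x$delta_AIC, x$delta_BIC, x$preferred["AIC"],
              x$preferred["BIC"]))
  invisible(x)
}

#' Model-predicted stage means
#'
#' Evaluates the fixed-effect trajectory `gamma_00 + gamma_10 * time +
#' gamma_20 * time2` at the four stage codings.
#'
#' @param fit A `growth_fit`.
#' @return A `data.frame` with `stage`, `time`, `time2`, `predicted`.
#' @export
predicted_trajectory <- function(fit) {
  tc <- build_time_codes(1:4)
  tc$predicted <- fit$gamma_00 + fit$gamma_10 * tc$time +
    fit$gamma_20 * tc$time2
  tc
}
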