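test_that("time coding is the piecewise occasion coding", {
  tc <- build_time_codes(1:4)
  expect_equal(tc$time, 0:3)
  expect_equal(tc$time2, c(0, 0, 1, 2))
  expect_equal(build_time_codes(1)$time2, 0)
  expect_equal(build_time_codes(4)[, c("time", "time2")],
               data.frame(time = 3L, time2 = 2L))
  expect_error(build_time_codes(5), "1..4")
  # time2 only accumulates after the control period
  expect_true(all(diff(tc$time2) >= 0))
  expect_true(all(tc$time2[tc$stage <= 2] == 0))
})

test_that("noise-free data reproduce the OLS stage-mean trajectory", {
  df <- sim_growth_data(40, gamma = c(0.2, 0.05, 0.3), sd_pair = 0,
                        sd_ind = c(0, 0, 0), sd_res = 1e-3, seed = 40)
  fit <- fit_growth(df, "piecewise")
  tc <- build_time_codes(1:4)
  ols <- lm(score ~ time + time2,
            data = transform(df, time = tc$time[stage],
                             time2 = tc$time2[stage]))
  expect_equal(fit$gamma_00, unname(coef(ols)[1]), tolerance = 1e-4)
  expect_equal(fit$gamma_10, unname(coef(ols)[2]), tolerance = 1e-4)
  expect_equal(fit$gamma_20, unname(coef(ols)[3]), tolerance = 1e-4)
})

test_that("marginal likelihood matches the brute-force pair covariance", {
  df <- sim_growth_data(30, seed = 41)
  for (model in c("unconditional", "piecewise")) {
    fit <- fit_growth(df, model)
    expect_equal(fit$loglik, bruteforce_growth_loglik(fit),
                 tolerance = 1e-8)
  }
})

test_that("piecewise nests the unconditional model", {
  df <- sim_growth_data(200, seed = 42)
  a <- fit_growth(df, "unconditional")
  b <- fit_growth(df, "piecewise")
  expect_gte(b$loglik, a$loglik - 1e-6)
  cmp <- compare_growth_models(a, b)
  expect_gte(cmp$lrt, 0)
  expect_equal(cmp$lrt_df, b$n_parameters - a$n_parameters)
  # information criteria arithmetic
  expect_equal(b$AIC, -2 * b$loglik + 2 * b$n_parameters)
  expect_equal(b$BIC, -2 * b$loglik + b$n_parameters * log(b$n_observations))
  # identical fits tie
  self <- compare_growth_models(b, b)
  expect_equal(self$delta_loglik, 0)
  expect_equal(unname(self$preferred["AIC"]), "tie")
  expect_error(compare_growth_models(a, fit_growth(df[-(1:8), ],
                                                   "piecewise")),
               "different numbers")
})

test_that("slope-change recovery at the study design size", {
  # mean gamma_20-hat within Monte-Carlo error of truth, and the model's
  # reported SE consistent with the empirical spread
  nsim <- 60
  g20 <- numeric(nsim)
  se20 <- numeric(nsim)
  for (i in seq_len(nsim)) {
    df <- sim_growth_data(375, gamma = c(0, 0, 0.07), seed = 100 + i)
    fit <- fit_growth(df, "piecewise")
    g20[i] <- fit$gamma_20
    se20[i] <- fit$se_20
  }
  mc_se <- sd(g20) / sqrt(nsim)
  expect_lt(abs(mean(g20) - 0.07), 2 * mc_se)
  expect_lt(abs(sd(g20) - mean(se20)) / sd(g20), 0.25)
})

test_that("model comparison detects a real slope change and calibrates", {
  # strong true change: piecewise preferred by LRT in nearly all runs
  hits <- 0
  nsim <- 25
  for (i in seq_len(nsim)) {
    df <- sim_growth_data(400, gamma = c(0, 0, 0.2), seed = 300 + i)
    cmp <- compare_growth_models(fit_growth(df, "unconditional"),
                                 fit_growth(df, "piecewise"))
    hits <- hits + (cmp$lrt_p < 0.05)
  }
  expect_gte(hits / nsim, 0.95)
  # no change: rejections do not exceed the nominal level (the LRT is
  # conservative here because variance components sit on the boundary)
  rejections <- 0
  nsim0 <- 40
  for (i in seq_len(nsim0)) {
    df <- sim_growth_data(150, gamma = c(0, 0.05, 0), sd_ind = c(0.5, 0.1, 0),
                          seed = 500 + i)
    cmp <- compare_growth_models(fit_growth(df, "unconditional"),
                                 fit_growth(df, "piecewise"))
    rejections <- rejections + (cmp$lrt_p < 0.05)
  }
  expect_lte(rejections / nsim0,
             0.05 + 3 * sqrt(0.05 * 0.95 / nsim0))
})

test_that("predicted trajectories follow the fixed-effect arithmetic", {
  fake <- structure(list(gamma_00 = 0, gamma_10 = 0, gamma_20 = 0.07),
                    class = "growth_fit")
  tr <- predicted_trajectory(fake)
  expect_equal(tr$predicted, c(0, 0, 0.07, 0.14))
  fake$gamma_10 <- 0.1
  fake$gamma_20 <- 0
  tr <- predicted_trajectory(fake)
  expect_equal(diff(tr$predicted), rep(0.1, 3))   # collinear in time
  expect_equal(tr$predicted[1], fake$gamma_00)
})
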