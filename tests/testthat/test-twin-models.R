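test_that("intraclass correlation has the ANOVA limiting behaviour", {
  # identical members within pairs, pairs differ: ICC = 1
  n <- 40
  co <- data.frame(family_id = rep(sprintf("f%02d", 1:n), each = 2),
                   zygosity = rep(rep(c("MZ", "DZ"), length.out = n),
                                  each = 2),
                   twin_index = rep(1:2, n), sex = "F", age = 16, stage = 1,
                   score = rep(rnorm(n), each = 2))
  icc <- intraclass_correlation(co, 1)
  expect_equal(icc$r_mz, 1)
  expect_equal(icc$r_dz, 1)
  # independent members: ICC near 0
  set.seed(20)
  n <- 5000
  co <- data.frame(family_id = rep(sprintf("f%05d", 1:n), each = 2),
                   zygosity = rep(rep(c("MZ", "DZ"), each = 2), n / 2),
                   twin_index = rep(1:2, n), sex = "F", age = 16, stage = 1,
                   score = rnorm(2 * n))
  icc <- intraclass_correlation(co, 1)
  expect_lt(abs(icc$r_mz), 2 / sqrt(icc$n_mz_pairs))
  expect_gt(icc$p_mz, 0.001)
})

test_that("ICCs recover the generating twin correlations at large n", {
  # baseline well-being structure: r_mz 0.55, r_dz 0.32
  p <- stage1_params(a2 = 0.46, c2 = 0.09, e2 = 0.45)
  co <- simulate_cohort(50000, 50000, params = p, seed = 21)
  icc <- intraclass_correlation(co, 1)
  expect_equal(icc$r_mz, 0.55, tolerance = 0.02)
  expect_equal(icc$r_dz, 0.32, tolerance = 0.02)
})

test_that("Falconer estimates follow the moment formulas exactly", {
  f <- falconer_estimates(0.55, 0.32)
  expect_equal(f$a2, 0.46)
  expect_equal(f$c2, 0.09)
  expect_equal(f$e2, 0.45)
  expect_false(f$out_of_bounds)
  # equal correlations: no genetic variance
  f <- falconer_estimates(0.4, 0.4)
  expect_equal(f$a2, 0)
  expect_equal(f$c2, 0.4)
  # pure-additive limit
  f <- falconer_estimates(1, 0.5)
  expect_equal(unlist(f[c("a2", "c2", "e2")]), c(a2 = 1, c2 = 0, e2 = 0))
  # identity holds exactly for arbitrary inputs, flagged when out of bounds
  set.seed(22)
  for (i in 1:25) {
    r <- sort(runif(2, -1, 1))
    f <- falconer_estimates(r[1], r[2])
    expect_identical(f$a2 + f$c2 + f$e2, 1)
  }
  f <- falconer_estimates(0.9, 0.1, truncated = TRUE)  # a2 = 1.6: flagged
  expect_true(f$out_of_bounds)
  expect_equal(f$truncated$a2 + f$truncated$c2 + f$truncated$e2, 1)
})

test_that("univariate ML recovers null and interior generating values", {
  # pure-E data: fitted A and C collapse to zero
  z <- matrix(0, 4, 4)
  p <- ace_loadings(z, z, diag(4))
  co <- simulate_cohort(10000, 10000, params = p, seed = 23)
  fit <- fit_univariate_ace(co, 1)
  expect_lt(fit$components$A[1, 1], 0.02)
  expect_lt(fit$components$C[1, 1], 0.02)
  expect_gt(fit$components$E[1, 1], 0.97)

  # interior values: ML and Falconer-from-ICC agree at large n
  p <- stage1_params(a2 = 0.4, c2 = 0.2, e2 = 0.4)
  co <- simulate_cohort(20000, 20000, params = p, seed = 24)
  fit <- fit_univariate_ace(co, 1)
  icc <- intraclass_correlation(co, 1)
  fal <- falconer_estimates(icc$r_mz, icc$r_dz)
  expect_equal(fit$components$A[1, 1], 0.4, tolerance = 0.03)
  expect_equal(fit$components$A[1, 1], fal$a2, tolerance = 0.03)
  expect_equal(fit$components$C[1, 1], fal$c2, tolerance = 0.03)
  expect_equal(fit$components$E[1, 1], fal$e2, tolerance = 0.03)
})

test_that("the optimum is a genuine likelihood maximum", {
  p <- stage1_params(a2 = 0.48, c2 = 0.07, e2 = 0.45)
  co <- simulate_cohort(2000, 2000, params = p, seed = 25)
  fit <- fit_univariate_ace(co, 1)
  # at least as good as the generating parameters on the same data
  gen_par <- c(a = sqrt(0.48), c = sqrt(0.07), e = sqrt(0.45))
  expect_gte(-fit$nll(gen_par), -1e9)
  expect_gte(fit$loglik, -fit$nll(gen_par))
  # refitting from the optimum cannot improve materially
  refit <- optim(fit$par_hat, fit$nll, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(-refit$value - fit$loglik, 1e-6)
  # pair floor enforced
  expect_error(fit_univariate_ace(co[1:80, ], 1, min_pairs = 20), "20")
})

test_that("profile-likelihood intervals bracket, clamp and shrink", {
  p <- stage1_params(a2 = 0.48, c2 = 0, e2 = 0.52)
  small <- simulate_cohort(167, 208, params = p, seed = 26)
  fit_s <- fit_univariate_ace(small, 1)
  ci_s <- likelihood_ci(fit_s, "a2")
  expect_lte(ci_s$lower, ci_s$estimate)
  expect_gte(ci_s$upper, ci_s$estimate)
  # a component generated at zero gets a boundary lower bound of 0.00
  ci_c <- likelihood_ci(fit_s, "c2")
  expect_equal(ci_c$lower, 0)
  big <- simulate_cohort(100000, 100000, params = p, seed = 27)
  fit_b <- fit_univariate_ace(big, 1)
  ci_b <- likelihood_ci(fit_b, "a2")
  width_s <- ci_s$upper - ci_s$lower
  width_b <- ci_b$upper - ci_b$lower
  expect_gt(width_s / width_b, 5)
})
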