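test_that("cohort structure matches the twin design", {
  co <- simulate_cohort(167, 208, seed = 1)
  expect_equal(nrow(co), 2 * (167 + 208) * 4)
  key <- paste(co$family_id, co$twin_index, co$stage)
  expect_false(any(duplicated(key)))
  expect_equal(length(unique(paste(co$family_id, co$twin_index))), 750)
  # zygosity, sex and age shared within pair; same-sex pairs only
  per_fam <- split(co, co$family_id)
  one <- per_fam[[1]]
  for (fam in per_fam[1:20]) {
    expect_equal(length(unique(fam$sex)), 1)
    expect_equal(length(unique(fam$age)), 1)
    expect_equal(sort(unique(fam$twin_index)), 1:2)
  }
  expect_true(all(co$age >= 14 & co$age <= 19))
  expect_setequal(unique(co$stage), 1:4)
})

test_that("identical seed gives byte-identical cohorts", {
  a <- simulate_cohort(30, 30, seed = 99)
  b <- simulate_cohort(30, 30, seed = 99)
  expect_identical(a, b)
  c <- simulate_cohort(30, 30, seed = 100)
  expect_false(identical(a$score, c$score))
})

test_that("degenerate parameters are rejected", {
  z <- matrix(0, 4, 4)
  p <- ace_loadings(z, z, diag(c(1, 1, 1, 0)))  # stage 4 has no variance
  expect_error(simulate_cohort(5, 5, params = p, seed = 1), "degenerate")
})

test_that("E-only twins are uncorrelated and standard normal", {
  z <- matrix(0, 4, 4)
  p <- ace_loadings(z, z, diag(4))
  co <- simulate_cohort(4000, 4000, params = p, seed = 2)
  pm <- pair_matrix(co)
  cross <- cor(pm$MZ[, 1:4], pm$MZ[, 5:8])
  expect_lt(max(abs(cross)), 3 / sqrt(4000))
  expect_equal(sd(pm$MZ[, 1]), 1, tolerance = 0.05)
})

test_that("empirical pair covariance converges to the theoretical one", {
  p <- twist_loadings("wellbeing")
  err <- sapply(c(2000, 32000), function(n) {
    co <- simulate_cohort(n, n, params = p, seed = 7)
    pm <- pair_matrix(co)
    e <- 0
    for (z in c("MZ", "DZ")) {
      emp <- cov(pm[[z]])
      e <- max(e, max(abs(emp - theoretical_pair_covariance(p, z))))
    }
    e
  })
  expect_lt(err[2], 0.02)          # large-n agreement
  expect_lt(err[2], err[1])        # error shrinks with n
})

test_that("MZ cross-twin correlations dominate DZ when A is present", {
  co <- simulate_cohort(20000, 20000, seed = 3)
  pm <- pair_matrix(co)
  r_mz <- cor(pm$MZ[, 1:4], pm$MZ[, 5:8])
  r_dz <- cor(pm$DZ[, 1:4], pm$DZ[, 5:8])
  # generating A loadings are nonzero for every stage pair reached by A1
  expect_true(all(diag(r_mz) > diag(r_dz)))
  expect_gt(mean(r_mz > r_dz), 0.9)
})

test_that("trajectory and covariate effects shift the means as coded", {
  traj <- mean_trajectory(baseline_mean = 1, control_increment = 0,
                          intervention_increment = 0.5, sex_effect = 0.3)
  co <- simulate_cohort(4000, 4000, trajectory = traj, seed = 4)
  m <- tapply(co$score, co$stage, mean)
  expect_equal(unname(m["3"] - m["2"]), 0.5, tolerance = 0.05)
  expect_equal(unname(m["4"] - m["3"]), 0.5, tolerance = 0.05)
  sex_gap <- mean(co$score[co$sex == "F"]) - mean(co$score[co$sex == "M"])
  expect_lt(abs(sex_gap - 0.3), 0.05)
})

test_that("missingness is MCAR at the configured per-stage rates", {
  co <- simulate_cohort(165, 165, seed = 5)
  expect_identical(apply_missingness(co, rep(0, 4), seed = 1), co)
  # attrition calibrated to leave ~155 of 165 MZ pairs complete at stage 3
  rate3 <- 1 - 155 / 165
  com <- apply_missingness(co, c(0, 0, rate3, 0), seed = 6)
  mz3 <- com[com$zygosity == "MZ" & com$stage == 3, ]
  complete_pairs <- sum(tapply(!is.na(mz3$score), mz3$family_id, all))
  # binomial 99% bounds around 165 * (155/165)^2
  p_complete <- (1 - rate3)^2
  bounds <- qbinom(c(0.005, 0.995), 165, p_complete)
  expect_gte(complete_pairs, bounds[1])
  expect_lte(complete_pairs, bounds[2])
  # deterministic mask
  expect_identical(apply_missingness(co, c(0, 0, rate3, 0), seed = 6), com)
})
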