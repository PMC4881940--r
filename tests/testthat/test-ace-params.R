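test_that("loadings container enforces triangularity and positivity", {
  m <- diag(4)
  bad <- m
  bad[1, 3] <- 0.2
  expect_error(ace_loadings(bad, m, m), "lower triangular")
  expect_error(proportions_to_loadings(-m, m, m), "negative")
  p <- ace_loadings(m * 0.6, m * 0.3, m * 0.74)
  expect_equal(stage_variances(p), rep(0.6^2 + 0.3^2 + 0.74^2, 4))
})

test_that("pair covariance has the E-only and A-only limiting forms", {
  z <- matrix(0, 4, 4)
  e_only <- ace_loadings(z, z, diag(4))
  for (zyg in c("MZ", "DZ")) {
    sig <- theoretical_pair_covariance(e_only, zyg)
    expect_equal(sig, diag(8))
  }
  a_only <- ace_loadings(diag(4), z, z)
  sig <- theoretical_pair_covariance(a_only, "MZ")
  expect_equal(sig[1:4, 5:8], diag(4))   # MZ correlation 1 at every stage
  sig_dz <- theoretical_pair_covariance(a_only, "DZ")
  expect_equal(sig_dz[1:4, 5:8], 0.5 * diag(4))
})

test_that("published-table loadings imply unit variances and the MZ-DZ gap", {
  for (outcome in c("wellbeing", "mentalhealth")) {
    tab <- twist_components(outcome)
    p <- twist_loadings(outcome)
    sig_mz <- theoretical_pair_covariance(p, "MZ")
    sig_dz <- theoretical_pair_covariance(p, "DZ")
    expect_true(isSymmetric(sig_mz))
    expect_gte(min(eigen(sig_mz, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-12)
    # totals are rounded to 2 dp in the source table
    expect_equal(unname(diag(sig_mz)[1:4]), rep(1, 4), tolerance = 0.02)
    gap <- diag(sig_mz[1:4, 5:8] - sig_dz[1:4, 5:8])
    expect_equal(unname(gap), unname(0.5 * rowSums(tab$A)),
                 tolerance = 1e-12)
  }
})

test_that("MZ minus DZ pair covariance is exactly half the A covariance", {
  set.seed(42)
  for (i in 1:20) {
    mk <- function() {
      m <- matrix(rnorm(16, sd = 0.5), 4, 4)
      m[upper.tri(m)] <- 0
      m
    }
    p <- ace_loadings(mk(), mk(), mk())
    dlt <- theoretical_pair_covariance(p, "MZ") -
      theoretical_pair_covariance(p, "DZ")
    expect_equal(dlt[1:4, 1:4], matrix(0, 4, 4))
    expect_equal(dlt[1:4, 5:8], 0.5 * tcrossprod(p$lambda_a))
  }
})

test_that("standardized components behave as proportions", {
  # diagonal unit loadings: each stage fully explained by its own factors
  p <- ace_loadings(diag(4) * 0.5, diag(4) * 0.5, diag(4) * sqrt(0.5))
  comp <- standardize_components(p)
  expect_equal(unname(diag(comp$A)), rep(0.25, 4))
  expect_equal(unname(comp$totals[, "E"]), rep(0.5, 4))
  expect_equal(unname(rowSums(comp$totals)), rep(1, 4))

  # scale invariance
  p2 <- ace_loadings(p$lambda_a * 3, p$lambda_c * 3, p$lambda_e * 3)
  expect_equal(standardize_components(p2)$A, comp$A)

  # published-table round trip: totals reproduce the table's totals
  tab <- twist_components("wellbeing")
  comp <- standardize_components(twist_loadings("wellbeing"))
  expect_equal(unname(comp$totals[, "A"]), unname(rowSums(tab$A)),
               tolerance = 0.02)
  expect_equal(unname(comp$totals[, "E"]), unname(rowSums(tab$E)),
               tolerance = 0.02)
})

test_that("stage-specific proportion reproduces the worked statistics", {
  wb <- twist_components("wellbeing")
  mh <- twist_components("mentalhealth")
  # .20 / (.22 + .06 + .20) and .38 / (.16 + .09 + .38)
  expect_equal(round(stage_specific_proportion(wb$E, stage = 3), 2), 0.42)
  expect_equal(round(stage_specific_proportion(mh$E, stage = 3), 2), 0.60)
  # stage 1 has only its own factor
  expect_equal(stage_specific_proportion(wb$E, stage = 1), 1)
  # zero denominator rejected
  z <- matrix(0, 4, 4)
  expect_error(stage_specific_proportion(z, stage = 2), "no variance")
})
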