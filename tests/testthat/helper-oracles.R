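# Shared fixtures and independent oracles used across the suite.

# 4-stage loadings whose first stage has the given standardized structure;
# later stages are pure-E so the object stays valid.
stage1_params <- function(a2, c2, e2) {
  mk <- function(v) {
    m <- diag(c(sqrt(v), 1, 1, 1))
    if (v == 0) m[1, 1] <- 0
    m
  }
  la <- diag(c(sqrt(a2), 0, 0, 0))
  lc <- diag(c(sqrt(c2), 0, 0, 0))
  le <- diag(c(sqrt(e2), 1, 1, 1))
  ace_loadings(la, lc, le)
}

# A bare cohort frame around given latent scores (single stage), for the
# item-measurement tests.
latent_frame <- function(score) {
  n <- length(score)
  data.frame(family_id = sprintf("f%05d", seq_len(n)), zygosity = "MZ",
             twin_index = 1L, sex = "F", age = 16, stage = 1L,
             score = score, stringsAsFactors = FALSE)
}

# Numerical-integration oracle for the graded-threshold item model:
# Pearson correlation between the scored scale and a standard-normal
# latent, integrating the threshold model over the latent distribution.
threshold_model_cor <- function(loading, n_items, point_scale) {
  tau <- seq(-1.5, 1.5, length.out = point_scale - 1)
  s <- sqrt(1 - loading^2)
  y <- seq(-8, 8, by = 0.005)
  w <- dnorm(y) * 0.005
  w <- w / sum(w)
  # per-item category probabilities as a function of the latent
  cump <- sapply(tau, function(t) pnorm((t - loading * y) / s))
  probs <- cbind(cump, 1) - cbind(0, cump)      # n_grid x K
  k <- seq_len(point_scale)
  m1 <- probs %*% k                              # E[resp | y]
  m2 <- probs %*% k^2
  v1 <- m2 - m1^2                                # Var[resp | y]
  mu <- sum(w * m1)
  cov_y <- sum(w * m1 * y)                       # E[y m1(y)], E[y] = 0
  var_score <- sum(w * (m1 - mu)^2) + sum(w * v1) / n_items
  cov_y / sqrt(var_score)
}

# Simulate three-level growth data with known fixed and random effects.
sim_growth_data <- function(n_pairs, gamma = c(0, 0, 0.07),
                            sd_pair = 0.3, sd_ind = c(0.5, 0.1, 0.1),
                            sd_res = 0.4, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    tc <- build_time_codes(1:4)
    rows <- expand.grid(twin_index = 1:2, stage = 1:4,
                        pair = seq_len(n_pairs))
    rows$family_id <- sprintf("f%05d", rows$pair)
    u_pair <- rnorm(n_pairs, 0, sd_pair)
    ind_key <- paste(rows$family_id, rows$twin_index)
    inds <- unique(ind_key)
    u_ind <- matrix(rnorm(length(inds) * 3), ncol = 3) %*% diag(sd_ind)
    rownames(u_ind) <- inds
    t1 <- tc$time[rows$stage]
    t2 <- tc$time2[rows$stage]
    rows$score <- gamma[1] + gamma[2] * t1 + gamma[3] * t2 +
      u_pair[rows$pair] +
      u_ind[ind_key, 1] + u_ind[ind_key, 2] * t1 + u_ind[ind_key, 3] * t2 +
      rnorm(nrow(rows), 0, sd_res)
    rows[, c("family_id", "twin_index", "stage", "score")]
  })
}

# Brute-force marginal Gaussian log-likelihood of a fitted growth model:
# rebuilds each pair's full covariance (pair intercept + individual
# random effects + residual) from the fitted variance components and sums
# exact multivariate-normal densities. Independent of lme4's internal
# profiled-deviance computation.
bruteforce_growth_loglik <- function(gf) {
  m <- gf$fit
  df <- m@frame
  X <- stats::model.matrix(m)
  beta <- lme4::fixef(m)
  vc <- lme4::VarCorr(m)
  G_ind <- as.matrix(vc$individual)
  re_cols <- rownames(vc$individual)
  g_pair <- as.numeric(vc$family_id[1, 1])
  s2 <- stats::sigma(m)^2
  resid <- df$score - as.vector(X %*% beta)
  ll <- 0
  for (fam in unique(df$family_id)) {
    idx <- which(df$family_id == fam)
    n <- length(idx)
    V <- diag(s2, n) + g_pair
    design <- cbind(`(Intercept)` = 1, time = df$time[idx],
                    time2 = if ("time2" %in% names(df)) df$time2[idx] else 0)
    for (ind in unique(df$individual[idx])) {
      j <- which(df$individual[idx] == ind)
      Zi <- design[j, re_cols, drop = FALSE]
      V[j, j] <- V[j, j] + Zi %*% G_ind %*% t(Zi)
    }
    r <- resid[idx]
    ll <- ll - 0.5 * (n * log(2 * pi) +
                      as.numeric(determinant(V)$modulus) +
                      sum(r * solve(V, r)))
  }
  ll
}
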