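#' Mean trajectory of a staged intervention study
#'
#' Piecewise-linear mean structure over the four assessment occasions:
#' flat-or-drifting through the control period (`control_increment` per
#' occasion) with an additional per-occasion increment once the
#' intervention starts. The occasion coding matches the piecewise growth
#' model: time = (0, 1, 2, 3), post-intervention time = (0, 0, 1, 2).
#'
#' @param baseline_mean Mean score at baseline.
#' @param control_increment Change per occasion throughout the study
#'   (default 0: no change during the control period).
#' @param intervention_increment Additional change per occasion from the
#'   intervention stage onward.
#' @param age_effect Mean effect per year of age (applied to age centered
#'   at the cohort mean).
#' @param sex_effect Mean difference, female minus male.
#' @param stage_times Assessment occasions in weeks; strictly increasing,
#'   length 4.
#' @return An object of class `mean_trajectory`.
#' @export
mean_trajectory <- function(baseline_mean = 0, control_increment = 0,
                            intervention_increment = 0, age_effect = 0,
                            sex_effect = 0, stage_times = c(1, 4, 7, 10)) {
  if (length(stage_times) != 4 || any(diff(stage_times) <= 0)) {
    stop("stage_times must be four strictly increasing values")
  }
  out <- list(baseline_mean = baseline_mean,
              control_increment = control_increment,
              intervention_increment = intervention_increment,
              age_effect = age_effect, sex_effect = sex_effect,
              stage_times = stage_times)
  class(out) <- "mean_trajectory"
  out
}

# Stage means before covariate effects, in occasion coding.
trajectory_stage_means <- function(trajectory) {
  tc <- build_time_codes(1:4)
  trajectory$baseline_mean +
    trajectory$control_increment * tc$time +
    trajectory$intervention_increment * tc$time2
}

#' Simulate a longitudinal twin cohort
#'
#' Draws same-sex twin pairs whose stacked four-stage scores follow the
#' exact joint normal distribution implied by a Cholesky ACE loading set
#' ([theoretical_pair_covariance()]), with a piecewise mean trajectory and
#' age/sex mean effects. One 8-vector is drawn per pair from the Cholesky
#' factor of the pair covariance, so the generating covariance is exact,
#' not approximate. Ages are drawn normal and truncated to \[14, 19\],
#' shared within pair; sex is shared within pair (same-sex design).
#'
#' @param n_mz,n_dz Number of monozygotic / dizygotic pairs.
#' @param params An [ace_loadings] object (4 stages).
#' @param trajectory A [mean_trajectory] object.
#' @param age_mean,age_sd Age distribution in years.
#' @param female_fraction Probability a pair is female.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A long-format `data.frame` with columns `family_id`, `zygosity`,
#'   `twin_index`, `sex`, `age`, `stage`, `score`: one row per individual
#'   per stage, `2 * (n_mz + n_dz) * 4` rows in total.
#' @export
simulate_cohort <- function(n_mz, n_dz, params = twist_loadings("wellbeing"),
                            trajectory = mean_trajectory(),
                            age_mean = 16.55, age_sd = 0.51,
                            female_fraction = 0.58, seed = NULL) {
  stopifnot(n_mz >= 1, n_dz >= 1,
            female_fraction >= 0, female_fraction <= 1,
            inherits(params, "ace_loadings"), params$n_stages == 4)
  tv <- stage_variances(params)
  if (any(tv <= 0)) {
    stop("degenerate params: zero total variance at stage ", which(tv <= 0)[1])
  }
  with_seed(seed, {
    sim_group <- function(n, zygosity, id_offset) {
      sigma <- theoretical_pair_covariance(params, zygosity)
      L <- t(chol(sigma + diag(1e-12, 8)))
      dev <- L %*% matrix(stats::rnorm(8 * n), nrow = 8)   # 8 x n
      age <- stats::rnorm(n, age_mean, age_sd)
      age <- pmin(pmax(age, 14), 19)
      sex <- ifelse(stats::runif(n) < female_fraction, "F", "M")
      stage_mu <- trajectory_stage_means(trajectory)
      fam <- sprintf("%s%04d", ifelse(zygosity == "MZ", "mz", "dz"),
                     id_offset + seq_len(n))
      df <- data.frame(
        family_id = rep(fam, each = 8),
        zygosity = zygosity,
        twin_index = rep(rep(1:2, each = 4), n),
        sex = rep(sex, each = 8),
        age = rep(age, each = 8),
        stage = rep.int(rep(1:4, 2), n),
        stringsAsFactors = FALSE)
      mu <- stage_mu[df$stage] +
        trajectory$age_effect * (df$age - age_mean) +
        trajectory$sex_effect * (df$sex == "F")
      df$score <- mu + as.vector(dev)
      df
    }
    rbind(sim_group(n_mz, "MZ", 0L), sim_group(n_dz, "DZ", 0L))
  })
}

#' Remove scores completely at random, per stage
#'
#' Missing-completely-at-random attrition: each individual-stage score is
#' set missing independently with the stage's rate. Pair structure is kept
#' (rows remain; `score` becomes `NA`), matching how partial data enter the
#' full-information twin likelihood.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param rate_per_stage Four proportions in \[0, 1).
#' @param seed Integer seed for a reproducible missingness mask.
#' @return The cohort with missing scores.
#' @export
apply_missingness <- function(cohort, rate_per_stage, seed = NULL) {
  stopifnot(length(rate_per_stage) == 4,
            all(rate_per_stage >= 0), all(rate_per_stage < 1))
  with_seed(seed, {
    u <- stats::runif(nrow(cohort))
    drop <- u < rate_per_stage[cohort$stage]
    cohort$score[drop] <- NA_real_
    cohort
  })
}

#' Write / read a cohort as long-format CSV
#'
#' The interchange format has one row per individual, stage and outcome:
#' `family_id,zygosity,twin_index,sex,age,stage,outcome,value`.
#'
#' @param cohort A cohort `data.frame` with a `score` column (or already in
#'   outcome/value form).
#' @param path File path.
#' @param outcome Name recorded in the `outcome` column when converting
#'   from a `score` column.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a cohort `data.frame` (wide in `score` if
#'   the file holds a single outcome, else long with `outcome`/`value`).
#' @export
write_cohort_csv <- function(cohort, path, outcome = "score") {
  df <- cohort
  if ("score" %in% names(df)) {
    df$outcome <- outcome
    df$value <- df$score
    df$score <- NULL
  }
  cols <- c("family_id", "zygosity", "twin_index", "sex", "age", "stage",
            "outcome", "value")
  utils::write.csv(df[, intersect(cols, names(df))], path, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("outcome" %in% names(df) && length(unique(df$outcome)) == 1) {
    df$score <- df$value
    df$outcome <- NULL
    df$value <- NULL
  }
  df
}
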