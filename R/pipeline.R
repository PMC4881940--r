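# Config-driven end-to-end run: simulate -> preprocess -> twin models ->
# growth models -> derived statistics, with every stochastic step seeded
# and all tables written as CSV next to a run manifest.

pipeline_defaults <- function() {
  list(
    output_dir = "results",
    generator = list(
      seed = NULL,
      n_mz = 167L, n_dz = 208L,
      age_mean = 16.55, age_sd = 0.51, female_fraction = 0.58,
      # individual-stage attrition chosen so complete-pair counts track a
      # realistic per-stage dropout profile
      missingness = c(0.006, 0.021, 0.037, 0.009),
      outcomes = list(
        wellbeing = list(
          proportions = "wellbeing",
          trajectory = list(baseline_mean = 0, control_increment = 0,
                            intervention_increment = 0.07,
                            age_effect = 0, sex_effect = 0)),
        mentalhealth = list(
          proportions = "mentalhealth",
          trajectory = list(baseline_mean = 0, control_increment = 0,
                            intervention_increment = 0.07,
                            age_effect = 0, sex_effect = 0)))),
    preprocessing = list(transform = TRUE, correct_age_sex = TRUE),
    models = list(stages = 1:4, ci_level = 0.95, restarts = 5,
                  missing_mode = "fiml", cholesky_ci = "none",
                  univariate_ci = TRUE, min_pairs = 20),
    power = list(run = FALSE, seed = NULL, a2 = 0.40, c2 = 0,
                 alpha = 0.05, reps = 2000))
}

deep_merge <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

resolve_outcome_params <- function(block, errors, outcome) {
  has_prop <- !is.null(block$proportions)
  has_load <- !is.null(block$loadings)
  if (has_prop && has_load) {
    return(list(params = NULL,
                errors = c(errors, paste0("outcome '", outcome,
                  "': supply exactly one of proportions or loadings"))))
  }
  if (!has_prop && !has_load) {
    return(list(params = NULL,
                errors = c(errors, paste0("outcome '", outcome,
                  "': needs a proportions table or loadings"))))
  }
  as_mat <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, function(r) {
      r <- unlist(r)
      c(r, rep(0, 4 - length(r)))
    }))
  }
  if (has_prop) {
    if (is.character(block$proportions)) {
      tab <- twist_components(block$proportions)
    } else {
      tab <- lapply(block$proportions[c("A", "C", "E")], as_mat)
    }
    sums <- rowSums(tab$A) + rowSums(tab$C) + rowSums(tab$E)
    bad <- which(abs(sums - 1) > 0.02)
    if (length(bad)) {
      return(list(params = NULL,
                  errors = c(errors, paste0("outcome '", outcome,
                    "': proportions sum to ", sprintf("%.2f", sums[bad[1]]),
                    " at stage ", bad[1], " (must be 1 +/- 0.02)"))))
    }
    params <- proportions_to_loadings(tab$A, tab$C, tab$E)
  } else {
    lt <- lapply(block$loadings[c("A", "C", "E")], as_mat)
    params <- tryCatch(ace_loadings(lt$A, lt$C, lt$E), error = function(e) e)
    if (inherits(params, "error")) {
      return(list(params = NULL,
                  errors = c(errors, paste0("outcome '", outcome, "': ",
                                            conditionMessage(params)))))
    }
  }
  list(params = params, errors = errors)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every default, resolves generating proportions/loadings for each
#' outcome, and reports all schema violations at once rather than
#' first-only. Every stochastic block must carry an explicit seed.
#'
#' @param config A nested list, or the path of a YAML file holding one.
#' @return The normalized config (invisibly carries resolved
#'   [ace_loadings] per outcome in `$generator$outcomes[[i]]$params`).
#'   Throws one error listing every violation if the config is invalid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- deep_merge(pipeline_defaults(), config)
  errors <- character()
  if (is.null(cfg$generator$seed)) {
    errors <- c(errors, "generator block: missing seed")
  }
  if (isTRUE(cfg$power$run) && is.null(cfg$power$seed)) {
    errors <- c(errors, "power block: missing seed")
  }
  g <- cfg$generator
  if (g$n_mz < 1 || g$n_dz < 1) {
    errors <- c(errors, "generator block: pair counts must be >= 1")
  }
  if (length(g$missingness) != 4 || any(g$missingness < 0) ||
      any(g$missingness >= 1)) {
    errors <- c(errors,
                "generator block: missingness must be four rates in [0, 1)")
  }
  for (nm in names(g$outcomes)) {
    res <- resolve_outcome_params(g$outcomes[[nm]], errors, nm)
    errors <- res$errors
    cfg$generator$outcomes[[nm]]$params <- res$params
  }
  if (!cfg$models$missing_mode %in% c("fiml", "complete")) {
    errors <- c(errors, "models block: missing_mode must be fiml or complete")
  }
  if (length(errors)) {
    stop("invalid pipeline config:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' Run the full twin-intervention analysis pipeline
#'
#' Executes, in order: cohort simulation per outcome, missingness,
#' preprocessing, intraclass correlations and Falconer estimates per
#' stage, univariate ACE fits per stage, the multivariate Cholesky ACE
#' fit, stage-specific innovation proportions, both growth models with
#' their comparison and predicted trajectories, and (optionally) the
#' twin-design power simulation. All report tables are written as CSV
#' under the configured output directory together with a YAML run
#' manifest (seeds, config hash, package version). Identical config and
#' seeds give identical tables.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @param output_dir Overrides the config's output directory.
#' @return A `run_report` list with all fitted objects and tables.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- validate_config(config)
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, tables = list())
  stage_lbl <- twist_stage_labels()

  icc_rows <- list(); fal_rows <- list(); uni_rows <- list()
  innov_rows <- list(); growth_rows <- list(); traj_rows <- list()

  outcomes <- names(cfg$generator$outcomes)
  for (i in seq_along(outcomes)) {
    nm <- outcomes[i]
    blk <- cfg$generator$outcomes[[nm]]
    g <- cfg$generator
    traj <- do.call(mean_trajectory, blk$trajectory)
    cohort <- simulate_cohort(g$n_mz, g$n_dz, blk$params, traj,
                              age_mean = g$age_mean, age_sd = g$age_sd,
                              female_fraction = g$female_fraction,
                              seed = g$seed + i)
    cohort <- apply_missingness(cohort, g$missingness, seed = g$seed + 100 + i)
    write_cohort_csv(cohort, file.path(out_dir, paste0("cohort_", nm, ".csv")),
                     outcome = nm)
    proc <- preprocess_cohort(cohort,
                              transform = cfg$preprocessing$transform,
                              correct_age_sex = cfg$preprocessing$correct_age_sex)
    utils::write.csv(
      proc[, c("family_id", "zygosity", "twin_index", "stage", "score")],
      file.path(out_dir, paste0("processed_", nm, ".csv")), row.names = FALSE)

    # twin similarity and univariate fits per stage
    for (s in cfg$models$stages) {
      icc <- intraclass_correlation(proc, s)
      icc_rows[[paste(nm, s)]] <- data.frame(
        outcome = nm, stage = stage_lbl[s],
        r_mz = round(icc$r_mz, 3), n_mz = icc$n_mz_pairs, p_mz = icc$p_mz,
        r_dz = round(icc$r_dz, 3), n_dz = icc$n_dz_pairs, p_dz = icc$p_dz)
      fal <- falconer_estimates(icc$r_mz, icc$r_dz)
      fal_rows[[paste(nm, s)]] <- data.frame(
        outcome = nm, stage = stage_lbl[s], a2 = fal$a2, c2 = fal$c2,
        e2 = fal$e2, out_of_bounds = fal$out_of_bounds)
      uni <- fit_univariate_ace(proc, s, min_pairs = cfg$models$min_pairs,
                                restarts = cfg$models$restarts)
      est <- c(uni$components$A[1, 1], uni$components$C[1, 1],
               uni$components$E[1, 1])
      if (isTRUE(cfg$models$univariate_ci)) {
        cis <- lapply(c("a2", "c2", "e2"), function(q)
          likelihood_ci(uni, q, level = cfg$models$ci_level))
        cell <- vapply(1:3, function(j)
          fmt_est_ci(est[j], cis[[j]]$lower, cis[[j]]$upper), "")
      } else {
        cell <- sprintf("%.2f", est)
      }
      uni_rows[[paste(nm, s)]] <- data.frame(
        outcome = nm, stage = stage_lbl[s],
        A = cell[1], C = cell[2], E = cell[3],
        loglik = uni$loglik, converged = uni$convergence)
    }

    # multivariate Cholesky decomposition
    chol_fit <- fit_cholesky_ace(proc, stages = cfg$models$stages,
                                 mode = cfg$models$missing_mode,
                                 min_pairs = cfg$models$min_pairs,
                                 restarts = cfg$models$restarts)
    ct <- components_table(chol_fit, ci = cfg$models$cholesky_ci,
                           level = cfg$models$ci_level)
    utils::write.csv(ct, file.path(out_dir, paste0("components_", nm, ".csv")),
                     row.names = FALSE)
    report$tables[[paste0("components_", nm)]] <- ct
    report[[paste0("cholesky_", nm)]] <- chol_fit
    for (src in c("A", "C", "E")) {
      for (s in 2:4) {
        tot <- chol_fit$components$totals[s, src]
        innov_rows[[paste(nm, src, s)]] <- data.frame(
          outcome = nm, source = src, stage = stage_lbl[s],
          stage_specific = if (tot > 1e-8)
            stage_specific_proportion(chol_fit$components, src, s)
            else NA_real_)
      }
    }

    # growth models run on the baseline-standardized composite, not the
    # twin-model scores: the per-stage normal-score and residualization
    # corrections remove stage means, which are exactly what the growth
    # model estimates
    growth_input <- cohort
    growth_input$score <- standardize_on_baseline(cohort$score, cohort$stage)
    uncond <- fit_growth(growth_input, "unconditional")
    piece <- fit_growth(growth_input, "piecewise")
    cmp <- compare_growth_models(uncond, piece)
    for (f in list(uncond, piece)) {
      growth_rows[[paste(nm, f$model)]] <- data.frame(
        outcome = nm, model = f$model, gamma_00 = f$gamma_00,
        gamma_10 = f$gamma_10, gamma_20 = f$gamma_20,
        se_10 = f$se_10, se_20 = f$se_20 %||% NA_real_,
        loglik = f$loglik, AIC = f$AIC, BIC = f$BIC,
        parameters = f$n_parameters, n_obs = f$n_observations)
    }
    report[[paste0("growth_", nm)]] <- list(unconditional = uncond,
                                            piecewise = piece,
                                            comparison = cmp)
    tr <- predicted_trajectory(piece)
    tr$outcome <- nm
    traj_rows[[nm]] <- tr
  }

  bind <- function(rows) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  report$tables$icc <- bind(icc_rows)
  report$tables$falconer <- bind(fal_rows)
  report$tables$univariate <- bind(uni_rows)
  report$tables$innovation <- bind(innov_rows)
  report$tables$growth <- bind(growth_rows)
  report$tables$trajectory <- bind(traj_rows)
  for (nm in c("icc", "falconer", "univariate", "innovation", "growth",
               "trajectory")) {
    utils::write.csv(report$tables[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }

  if (isTRUE(cfg$power$run)) {
    pw <- power_heritability(cfg$generator$n_mz, cfg$generator$n_dz,
                             a2 = cfg$power$a2, c2 = cfg$power$c2,
                             alpha = cfg$power$alpha, reps = cfg$power$reps,
                             seed = cfg$power$seed)
    report$power <- pw
    report$tables$power <- data.frame(
      n_mz = pw$design$n_mz, n_dz = pw$design$n_dz, a2 = pw$design$a2,
      c2 = pw$design$c2, alpha = pw$alpha, reps = pw$reps,
      power = pw$power, se = pw$se)
    utils::write.csv(report$tables$power, file.path(out_dir, "power.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("twinace")),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "output_dir")]),
    seeds = list(generator = cfg$generator$seed,
                 power = if (isTRUE(cfg$power$run)) cfg$power$seed else NULL),
    outcomes = outcomes,
    tables = paste0(c("icc", "falconer", "univariate", "innovation",
                      "growth", "trajectory",
                      paste0("components_", outcomes)), ".csv"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  report$manifest <- manifest
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Twin-intervention pipeline report\n")
  cat("Outcomes:", paste(x$manifest$outcomes, collapse = ", "), "\n")
  cat("Config hash:", x$manifest$config_hash, "\n")
  cat("Tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}
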