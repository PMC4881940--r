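# Reference values from the published TWIST design (Twins Well-Being
# Intervention Study): a 10-week online positive-activity intervention in
# adolescent same-sex twin pairs, assessed at Weeks 1/4/7/10
# (baseline / end of control / end of intervention / follow-up).
# These drive the simulator defaults and the worked statistics.

twist_stage_labels <- function() {
  c("baseline", "control", "intervention", "followup")
}

lower_tri_from_rows <- function(rows) {
  d <- length(rows)
  m <- matrix(0, d, d)
  for (i in seq_len(d)) m[i, seq_len(i)] <- rows[[i]]
  m
}

#' TWIST study design constants
#'
#' Pair counts, age distribution and sex composition of the TWIST cohort
#' (167 monozygotic and 208 dizygotic same-sex pairs, 750 individuals,
#' mean age 16.55, SD 0.51), used as simulator defaults.
#'
#' @return A list with `n_mz`, `n_dz`, `age_mean`, `age_sd`,
#'   `female_fraction`, and `stage_weeks` (assessment occasions in weeks).
#' @export
twist_design <- function() {
  list(n_mz = 167L, n_dz = 208L,
       age_mean = 16.55, age_sd = 0.51,
       female_fraction = 0.58,
       stage_weeks = c(1, 4, 7, 10))
}

#' Published standardized variance-component tables of the TWIST study
#'
#' The reported squared standardized contributions of the triangular ACE
#' factors (A1-A4, C1-C4, E1-E4) to each of the four assessment stages, for
#' the well-being and mental-health composites. Rows are stages
#' (baseline, control, intervention, follow-up); column `j` is factor `j`.
#' These proportions serve two roles: as worked inputs for the derived
#' innovation statistics, and (via [proportions_to_loadings()]) as
#' generating truth for simulation-based parameter recovery.
#'
#' @param outcome `"wellbeing"` or `"mentalhealth"`.
#' @return A list with lower-triangular 4 x 4 matrices `A`, `C`, `E`.
#' @examples
#' tab <- twist_components("wellbeing")
#' # share of intervention-stage E variance that is intervention-specific
#' stage_specific_proportion(tab$E, stage = 3)
#' @export
twist_components <- function(outcome = c("wellbeing", "mentalhealth")) {
  outcome <- match.arg(outcome)
  tabs <- switch(outcome,
    wellbeing = list(
      A = lower_tri_from_rows(list(
        0.48,
        c(0.48, 0.02),
        c(0.41, 0.03, 0.01),
        c(0.44, 0.03, 0.01, 0.00))),
      C = lower_tri_from_rows(list(
        0.07,
        c(0.05, 0.00),
        c(0.06, 0.00, 0.00),
        c(0.03, 0.00, 0.00, 0.00))),
      E = lower_tri_from_rows(list(
        0.44,
        c(0.23, 0.22),
        c(0.22, 0.06, 0.20),
        c(0.21, 0.07, 0.04, 0.18)))),
    mentalhealth = list(
      A = lower_tri_from_rows(list(
        0.24,
        c(0.26, 0.09),
        c(0.34, 0.01, 0.01),
        c(0.27, 0.01, 0.00, 0.00))),
      C = lower_tri_from_rows(list(
        0.13,
        c(0.05, 0.00),
        c(0.01, 0.00, 0.00),
        c(0.01, 0.03, 0.02, 0.00))),
      E = lower_tri_from_rows(list(
        0.63,
        c(0.20, 0.41),
        c(0.16, 0.09, 0.38),
        c(0.17, 0.08, 0.04, 0.38)))))
  lbl <- twist_stage_labels()
  for (nm in names(tabs)) {
    dimnames(tabs[[nm]]) <- list(lbl, paste0(nm, 1:4))
  }
  tabs
}

#' Generating loadings for a TWIST-like simulation
#'
#' Square-root loadings of the published standardized tables, giving a
#' simulated phenotype with (approximately) unit variance at every stage.
#'
#' @inheritParams twist_components
#' @return An [ace_loadings] object.
#' @export
twist_loadings <- function(outcome = c("wellbeing", "mentalhealth")) {
  tab <- twist_components(outcome)
  proportions_to_loadings(tab$A, tab$C, tab$E)
}
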