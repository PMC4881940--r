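#' Standardize repeated measures on their baseline distribution
#'
#' All stages are transformed by `(x - baseline_mean) / baseline_sd`, using
#' the moments of stage 1 (Week 1) only, so change over the study is
#' expressed in baseline standard-deviation units and the baseline column
#' has mean 0 and SD 1 by construction.
#'
#' @param scores Numeric vector of scores.
#' @param stage Integer vector of stages (1 = baseline), same length.
#' @return Standardized scores.
#' @export
standardize_on_baseline <- function(scores, stage) {
  stopifnot(length(scores) == length(stage))
  base <- scores[stage == 1 & !is.na(scores)]
  if (length(base) < 2) stop("need at least two non-missing baseline scores")
  s <- stats::sd(base)
  if (s == 0) stop("baseline SD is zero; cannot standardize")
  (scores - mean(base)) / s
}

#' van der Waerden normal scores
#'
#' Rank-based inverse normal transformation: the value with (average) rank
#' `r` among `n` non-missing values maps to `qnorm(r / (n + 1))`. Ties
#' share their average rank; missing values stay missing. The transform is
#' invariant to strictly monotone transformations of its input and removes
#' skew, which is why it is the standard normalization before twin
#' model-fitting on skewed questionnaire scores.
#'
#' @param values Numeric vector, possibly with ties and `NA`s.
#' @return Normal scores, same length.
#' @examples
#' van_der_waerden(c(10, 20, 30))  # qnorm(c(.25, .5, .75))
#' @export
van_der_waerden <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values")
  out <- rep(NA_real_, length(values))
  x <- values[ok]
  if (length(unique(x)) == 1) {
    warning("all values identical; normal scores are all zero")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x, ties.method = "average")
  out[ok] <- stats::qnorm(r / (n + 1))
  out
}

#' Residualize scores on age and sex
#'
#' Ordinary least-squares regression of the score on age and sex (main
#' effects), returning the residuals re-standardized to mean 0, SD 1 --
#' the standard pre-correction before twin analyses, since age and sex are
#' perfectly shared within same-sex pairs and would otherwise inflate the
#' twin resemblance attributed to C.
#'
#' @param scores Numeric vector.
#' @param age Numeric vector of ages.
#' @param sex Character or factor with two levels (e.g. "M"/"F").
#' @return Corrected scores; `NA` where any input was missing.
#' @export
residualize_age_sex <- function(scores, age, sex) {
  stopifnot(length(scores) == length(age), length(scores) == length(sex))
  sexf <- factor(sex)
  cc <- !is.na(scores) & !is.na(age) & !is.na(sexf)
  if (sum(cc) < 3) stop("need at least 3 complete cases")
  if (stats::sd(age[cc]) == 0 && nlevels(droplevels(sexf[cc])) < 2) {
    stop("age and sex are both constant; nothing to residualize on")
  }
  has_sex <- nlevels(droplevels(sexf[cc])) >= 2
  has_age <- stats::sd(age[cc]) > 0
  form <- stats::reformulate(c(if (has_age) "age", if (has_sex) "sexf"),
                             response = "scores")
  fit <- stats::lm(form, data = data.frame(scores, age, sexf)[cc, ])
  res <- stats::residuals(fit)
  s <- stats::sd(res)
  if (s < 1e-12) {
    warning("degenerate residual variance after age/sex correction")
    s <- 1
  }
  out <- rep(NA_real_, length(scores))
  out[cc] <- (res - mean(res)) / s
  out
}

#' Combine scale scores into well-being and mental-health composites
#'
#' Each scale is standardized on baseline, then the well-being composite is
#' the mean of the standardized SHS and BMSLSS scores and the mental-health
#' composite is the mean of the negated standardized MFQ and STAI6 scores
#' (negation so that higher values denote fewer symptoms of depression and
#' anxiety; a sign flip commutes with standardization). A composite is
#' computed only when both constituent scales are present at that stage.
#'
#' @param scores A `data.frame` with a `stage` column and scale-score
#'   columns among `SHS`, `BMSLSS`, `MFQ`, `STAI6`.
#' @return The input with `wellbeing` and/or `mentalhealth` columns added
#'   (whichever pair of scales is available).
#' @export
build_composites <- function(scores) {
  stopifnot("stage" %in% names(scores))
  z <- function(col) standardize_on_baseline(scores[[col]], scores$stage)
  out <- scores
  if (all(c("SHS", "BMSLSS") %in% names(scores))) {
    out$wellbeing <- (z("SHS") + z("BMSLSS")) / 2
  }
  if (all(c("MFQ", "STAI6") %in% names(scores))) {
    out$mentalhealth <- (-z("MFQ") - z("STAI6")) / 2
  }
  if (is.null(out$wellbeing) && is.null(out$mentalhealth)) {
    stop("need SHS+BMSLSS and/or MFQ+STAI6 columns")
  }
  out
}

#' Preprocess a cohort's scores for twin model-fitting
#'
#' The fixed correction pipeline applied to each outcome before
#' variance-component estimation: van der Waerden normal scores (per stage,
#' to correct skew), then residualization on age and sex (per stage,
#' pooling all individuals), re-standardized to mean 0, SD 1.
#'
#' @param cohort A cohort `data.frame` with columns `stage`, `age`, `sex`
#'   and `score`.
#' @param transform Apply the van der Waerden transform (default `TRUE`).
#' @param correct_age_sex Apply the age/sex residualization (default
#'   `TRUE`).
#' @return The cohort with `score` replaced by the corrected score.
#' @export
preprocess_cohort <- function(cohort, transform = TRUE,
                              correct_age_sex = TRUE) {
  out <- cohort
  for (s in sort(unique(out$stage))) {
    idx <- out$stage == s
    x <- out$score[idx]
    if (transform) x <- van_der_waerden(x)
    if (correct_age_sex) {
      x <- residualize_age_sex(x, out$age[idx], out$sex[idx])
    }
    out$score[idx] <- x
  }
  out
}
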