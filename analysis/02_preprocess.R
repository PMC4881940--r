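#!/usr/bin/env Rscript
# Preprocess the simulated cohorts for twin model-fitting: van der Waerden
# normal scores per stage (skew correction), then residualization on age
# and sex, re-standardized to mean 0 / SD 1.

library(twinace)

for (nm in c("wellbeing", "mentalhealth")) {
  cohort <- read_cohort_csv(file.path("results",
                                      paste0("cohort_", nm, ".csv")))
  proc <- preprocess_cohort(cohort)
  path <- file.path("results", paste0("processed_", nm, ".csv"))
  write.csv(proc[, c("family_id", "zygosity", "twin_index", "sex", "age",
                     "stage", "score")], path, row.names = FALSE)
  # growth models need the stage means intact: keep a baseline-standardized
  # version of the composite alongside the twin-model scores
  comp <- cohort
  comp$score <- standardize_on_baseline(cohort$score, cohort$stage)
  write.csv(comp[, c("family_id", "zygosity", "twin_index", "stage",
                     "score")],
            file.path("results", paste0("composite_", nm, ".csv")),
            row.names = FALSE)
  for (s in 1:4) {
    x <- proc$score[proc$stage == s]
    cat(sprintf("%s stage %d: mean %+.2e, SD %.3f, %d missing\n",
                nm, s, mean(x, na.rm = TRUE), sd(x, na.rm = TRUE),
                sum(is.na(x))))
  }
  cat("wrote", path, "\n")
}
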