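# Default pipeline configuration: a TWIST-like simulated cohort
# (167 MZ + 208 DZ same-sex pairs, four assessment stages) generated from
# the published standardized variance-component tables, with a flat
# control period and a 0.07-per-occasion intervention response.
output_dir: results
generator:
  seed: 20160526
  n_mz: 167
  n_dz: 208
  age_mean: 16.55
  age_sd: 0.51
  female_fraction: 0.58
  missingness: [0.006, 0.021, 0.037, 0.009]
  outcomes:
    wellbeing:
      proportions: wellbeing
      trajectory:
        baseline_mean: 0.0
        control_increment: 0.0
        intervention_increment: 0.07
        age_effect: 0.0
        sex_effect: 0.0
    mentalhealth:
      proportions: mentalhealth
      trajectory:
        baseline_mean: 0.0
        control_increment: 0.0
        intervention_increment: 0.07
        age_effect: 0.0
        sex_effect: 0.0
preprocessing:
  transform: true
  correct_age_sex: true
models:
  stages: [1, 2, 3, 4]
  ci_level: 0.95
  restarts: 5
  missing_mode: fiml
  cholesky_ci: none
  univariate_ci: true
  min_pairs: 20
power:
  run: false
  seed: 20160527
  a2: 0.40
  c2: 0.0
  alpha: 0.05
  reps: 2000
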