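---
title: "Methods: twin ACE variance components across an intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin ACE variance components across an intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The scientific question

When a well-being intervention is embedded between repeated assessments of
a twin cohort, two distinct things can change: the *mean* of the phenotype
(did people get happier?) and the *composition of individual differences*
(are the same genetic and environmental factors responsible for variation
before and after the intervention?). twinace implements the full analysis
chain for this design: a seeded simulator that generates twin cohorts with
a known, exact covariance structure; preprocessing of questionnaire
scores; twin variance-component estimation; a multivariate Cholesky
decomposition that separates transmitted from newly arising influence; a
piecewise multilevel growth model for the mean response; and a Monte-Carlo
power analysis for the classical twin design.

The default study conditions throughout are those of a published 10-week
online positive-activity intervention in adolescent twins: 167
monozygotic (MZ) and 208 dizygotic (DZ) same-sex pairs (750 individuals),
assessed at Weeks 1, 4, 7 and 10 (baseline, end of a control-activity
period, end of the intervention, and follow-up), ages
normal(16.55, 0.51), with well-being and mental-health composites built
from four questionnaire scales.

## The ACE model and its multivariate Cholesky form

The classical twin design decomposes phenotypic variance into additive
genetic (A), shared environmental (C) and non-shared environmental (E)
components using the contrast between MZ pairs (sharing all segregating
genes) and DZ pairs (sharing half on average). For a single measure with
loadings $a, c, e$, the within-pair covariance matrix is

$$\Sigma = \begin{pmatrix} a^2+c^2+e^2 & r_A a^2 + c^2 \\
r_A a^2 + c^2 & a^2+c^2+e^2 \end{pmatrix},
\qquad r_A = 1 \text{ (MZ)},\; 0.5 \text{ (DZ)}.$$

For the four repeated assessments the package uses the triangular
(Cholesky) factor model: lower-triangular loading matrices
$\Lambda_a, \Lambda_c, \Lambda_e$ (4×4, 30 free loadings) in which factor
$j$ may load only on stages $j, \dots, 4$. The implied joint covariance
of a pair's stacked eight scores has within-twin block
$\Lambda_a\Lambda_a' + \Lambda_c\Lambda_c' + \Lambda_e\Lambda_e'$ and
cross-twin block $r_A\,\Lambda_a\Lambda_a' + \Lambda_c\Lambda_c'$
(`theoretical_pair_covariance()`). The triangular ordering is what makes
the decomposition scientifically useful here: the diagonal loading of
stage 3 (the intervention stage) captures influence *newly arising* at
that stage, independent of everything transmitted from baseline and
control. The headline derived statistic,
`stage_specific_proportion()`, is the share of a source's variance at a
stage contributed by that stage's own factor — e.g. the fraction of
non-shared environmental variance at the intervention stage that is
intervention-specific.

Published tables report squared standardized contributions, so
`proportions_to_loadings()` maps such a table back to generating loadings
by element-wise square root (all signs positive — squares carry no sign
information), and `twist_components()` ships the reference tables used as
simulator defaults and as generating truth for recovery tests.

## Estimation

**Likelihood.** Both fitters maximize the two-group Gaussian pair
likelihood, parameterized by loadings rather than variances so implied
component matrices are positive semi-definite without constraints
(column signs are normalized to nonnegative diagonals afterwards). For
complete pairs the per-group stage means are exact ML under the
twin-exchangeable covariance (the constant vector is an eigendirection),
so they profile out and only loadings are optimized. With partially
missing stage vectors the default full-information mode evaluates each
pair's likelihood on its observed sub-vector, grouping pairs by
missingness pattern and carrying sufficient statistics per pattern, with
per-group stage means as free parameters.

**Optimization.** BFGS over the loadings from a moment-based start (the
Falconer-style block estimates $\hat A = 2(X_{MZ}-X_{DZ})$,
$\hat C = 2X_{DZ}-X_{MZ}$, $\hat E = W - \hat A - \hat C$, each projected
to its nearest PSD matrix and Cholesky-factored), plus five deterministic
rescaled restarts; restarts run as cheap scouting passes and the best is
polished at relative tolerance 1e-12. One-stage fits of the multivariate
code path agree with the dedicated univariate fitter to 1e-6
log-likelihood units (tested), and refitting from a reported optimum
never improves it materially.

**Confidence intervals** are profile likelihood: bounds where twice the
log-likelihood drop equals $\chi^2_1(0.95)$, found by bisection over a
penalized profile, clamped to $[0,1]$ for standardized quantities (the
familiar `.00` bounds of published tables). Profiling the 30-loading
model is expensive, so multivariate CIs are opt-in
(`components_table(fit, ci = "totals")`), while univariate CIs are cheap
and on by default in the pipeline.

**Simpler estimators.** `intraclass_correlation()` is the one-way
random-effects ANOVA ICC, $(MSB - MSW)/(MSB + MSW)$, the classical twin
convention (the double-entry Pearson correlation is a near-equivalent
alternative; the ANOVA form is used throughout). `falconer_estimates()`
applies the moment formulas $a^2 = 2(r_{MZ} - r_{DZ})$,
$c^2 = 2r_{DZ} - r_{MZ}$, $e^2 = 1 - r_{MZ}$; the identity
$a^2+c^2+e^2 = 1$ holds exactly and out-of-range estimates are flagged,
never silently clamped.

## Preprocessing

Scale scores are item means (reverse-keyed items mapped
$v \mapsto K+1-v$), missing unless at least half the items are present.
Each scale is standardized on its baseline moments; the well-being
composite averages standardized SHS and BMSLSS, the mental-health
composite averages the *negated* standardized MFQ and STAI-6 (negation
commutes with standardization and makes higher scores mean fewer
symptoms). Composites require both constituent scales at a stage; no
imputation is attempted.

Before twin model-fitting each outcome is put through van der Waerden
normal scores — rank $r$ of $n$ maps to $\Phi^{-1}(r/(n+1))$, average
ranks for ties (the conventional tie rule; the transform is applied per
stage and per outcome) — and then residualized on age and sex by OLS,
pooling all individuals, re-standardized to mean 0, SD 1. Age and sex are
perfectly shared within same-sex pairs, so uncorrected mean effects would
inflate the shared-environment estimate.

These per-stage corrections deliberately remove stage means. The growth
models therefore run on the baseline-standardized composites (stage means
intact), not on the twin-model scores — mirroring the usual practice of
correcting data "for twin analyses" while modeling the mean response on
the observed scale.

## The growth model for the mean response

Occasions are coded `time` = 0–3 and `time2` = (0, 0, 1, 2), so `time2`
starts accumulating when the intervention begins. The piecewise model is

$$y_{tij} = \gamma_{00} + \gamma_{10}\,\text{time} +
\gamma_{20}\,\text{time2} + u_{j} + v_{0ij} + v_{1ij}\,\text{time} +
v_{2ij}\,\text{time2} + \varepsilon_{tij}$$

with a pair-level random intercept $u_j$ and individual-level random
intercept and slopes (slopes vary at the individual level only); the
unconditional model drops the `time2` terms. Estimation is full ML (not
REML) via lme4 so the two models' likelihood-ratio comparison is valid;
a second optimizer run guards the nesting property against convergence to
a poorer optimum. t statistics use residual degrees of freedom
$n_{obs} - n_{fixed}$. Time is in occasion units, not weeks: a
per-occasion post-intervention increment of 0.07 baseline-SD units is the
effect scale of interest; users wanting week units can rescale the
codings. The exact marginal likelihood is verified in the test suite
against a brute-force construction of each pair's 8×8 covariance.

## The simulator

`simulate_cohort()` draws one 8-vector per pair from the exact joint
normal (Cholesky factor of the model-implied pair covariance) — exact and
fast, rather than summing separate A/C/E draws. Ages are
normal(16.55, 0.51) truncated to [14, 19] and shared within a pair; sex
is shared (same-sex design, 58% female pairs by default). Stage means
follow the piecewise trajectory (flat control period by default,
+0.07/occasion from the intervention onward) plus optional age and sex
mean effects. Missingness is completely at random per individual-stage;
the default rates (0.6%, 2.1%, 3.7%, 0.9%) give complete-pair counts that
track a realistic attrition profile. Item-level responses, when needed,
come from a graded-threshold model (item latent =
$\lambda\,\text{score} + \sqrt{1-\lambda^2}\,\text{noise}$, equally
spaced thresholds on $[-1.5, 1.5]$); this is simulator scaffolding for
testing the scoring pipeline, not a calibrated psychometric model, and no
claim is made that it reproduces any particular scale's internal
consistency.

What the simulator does *not* emulate: selection and attrition related to
the outcome (missingness is MCAR), cross-trait covariance between
well-being and mental health (the two outcomes are generated and analyzed
separately), activity compliance, opposite-sex pairs, and non-normal
latent distributions. Passing recovery tests on these synthetic cohorts
therefore demonstrates correctness of the estimators under the stated
model, not robustness to violations of it.

## Power analysis

`power_heritability()` simulates replicate univariate cohorts, fits ACE
and CE by ML, and refers the likelihood-ratio statistic to the 50:50
mixture of $\chi^2_0$ and $\chi^2_1$ (the tested variance component sits
on its boundary under the null), rejecting when
$0.5\,P(\chi^2_1 \ge LRT) < \alpha$. Type-I error calibrates to $\alpha$
within Monte-Carlo error (tested). The documented default for the
acceptance run assumes no shared environment ($c^2 = 0$). Under that
assumption the package computes ≈71% power for the 167 + 208 pair design
to detect $a^2 = 0.40$ at $\alpha = 0.05$ (2000 replicates; the analysis
scripts also show the strong sensitivity of this figure to the assumed
$c^2$, e.g. ≈80% at $c^2 = 0.10$): with true $c^2 = 0$ the CE comparison
model absorbs part of the genetic covariance into C, which is what limits
the test's power.

## Numerical choices and degenerate inputs

- Convergence: BFGS relative tolerance 1e-12 on the objective; scouting
  restarts at 1e-8.
- Loadings with zero diagonal are admissible (a factor may be absent);
  sign indeterminacy is resolved by flipping columns to nonnegative
  diagonals.
- A stage with zero variance, a zero baseline SD, an all-constant vector
  given to the normal-score transform, or collinear covariates in the
  residualization are rejected (or warned, where a defined degenerate
  answer exists: constant input yields all-zero normal scores).
- Profile bounds that reach 0 or 1 are reported clamped with a flag;
  intervals always contain the point estimate.
- ICC with zero between-pair variance is reported as computed (possibly
  negative) with a degeneracy flag.

## Problem sizes used in the checks

The test suite and acceptance script choose simulation sizes so each
quantity's Monte-Carlo error is well inside its assertion tolerance:
50,000 pairs per zygosity group for multivariate recovery (sampling error
on a standardized contribution ≈ 0.003), 100,000 pairs per group for
univariate recovery and CI-scaling checks, 2000 replicates for power
(binomial SE ≈ 0.01), and the exact study size (375 pairs) wherever the
claim concerns behaviour at the published design.

## Known limitations

- No ADE or sex-limitation variants, and no bivariate cross-trait model.
- MCAR missingness only; the FIML fitter handles missing-at-random data
  correctly but the simulator never generates informative missingness.
- Profile CIs for all 30 multivariate contributions are computationally
  heavy; published-table-style CI output is opt-in.
- The power tool addresses only the heritability test of the univariate
  design, the single power claim attached to this study design.
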