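#' Cholesky ACE factor loadings
#'
#' Container for the triangular factor-loading matrices of a multivariate
#' ACE model. Each of the three matrices is lower triangular with
#' `n_stages` rows: column `j` holds the loadings of factor `j` (A\emph{j},
#' C\emph{j} or E\emph{j}) on stages `j..n_stages`. Factor `j` therefore
#' contributes nothing before stage `j`, which is what separates variance
#' transmitted from earlier occasions from innovations arising at each
#' occasion.
#'
#' @param lambda_a,lambda_c,lambda_e Square lower-triangular matrices of
#'   additive-genetic, shared-environment and non-shared-environment factor
#'   loadings (same dimension; typically 4 x 4 for a four-stage study, 1 x 1
#'   for a univariate model).
#' @return An object of class `ace_loadings` with elements `lambda_a`,
#'   `lambda_c`, `lambda_e` and `n_stages`.
#' @examples
#' p <- ace_loadings(diag(4) * 0.6, diag(4) * 0.3, diag(4) * 0.74)
#' stage_variances(p)
#' @export
ace_loadings <- function(lambda_a, lambda_c, lambda_e) {
  mats <- list(lambda_a = as.matrix(lambda_a),
               lambda_c = as.matrix(lambda_c),
               lambda_e = as.matrix(lambda_e))
  d <- nrow(mats$lambda_a)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.numeric(m) || nrow(m) != d || ncol(m) != d) {
      stop(nm, " must be a ", d, " x ", d, " numeric matrix")
    }
    if (!is_lower_triangular(m)) {
      stop(nm, " must be lower triangular (factor j cannot load on stages before j)")
    }
  }
  out <- c(mats, list(n_stages = d))
  class(out) <- "ace_loadings"
  out
}

#' @export
print.ace_loadings <- function(x, ...) {
  cat("Cholesky ACE loadings,", x$n_stages, "stage(s)\n")
  tv <- stage_variances(x)
  cat("Implied stage variances:", paste(sprintf("%.3f", tv), collapse = " "), "\n")
  invisible(x)
}

#' Convert a standardized-contributions table to loadings
#'
#' Published multivariate twin results are usually reported as squared
#' standardized contributions: the proportion of each stage's phenotypic
#' variance explained by each triangular factor. This helper maps such a
#' table back to generating loadings by element-wise square root, taking all
#' signs positive (the published squares carry no sign information).
#'
#' @param prop_a,prop_c,prop_e Lower-triangular matrices of per-stage
#'   variance proportions for the A, C and E factors.
#' @return An [ace_loadings] object whose squared loadings reproduce the
#'   input proportions.
#' @export
proportions_to_loadings <- function(prop_a, prop_c, prop_e) {
  as_load <- function(m, nm) {
    m <- as.matrix(m)
    if (any(m < 0)) stop(nm, " contains negative proportions")
    sqrt(m)
  }
  ace_loadings(as_load(prop_a, "prop_a"),
               as_load(prop_c, "prop_c"),
               as_load(prop_e, "prop_e"))
}

#' Total phenotypic variance implied at each stage
#'
#' Row sums of squared loadings across the three factor sets.
#'
#' @param params An [ace_loadings] object.
#' @return Numeric vector of per-stage variances.
#' @export
stage_variances <- function(params) {
  stopifnot(inherits(params, "ace_loadings"))
  rowSums(params$lambda_a^2) + rowSums(params$lambda_c^2) +
    rowSums(params$lambda_e^2)
}

#' Model-implied twin-pair covariance matrix
#'
#' The joint covariance of the stacked stage scores of both members of a
#' twin pair. With `d` stages the result is `2d x 2d`: the within-twin
#' block is the full phenotypic covariance
#' \eqn{\Lambda_a\Lambda_a' + \Lambda_c\Lambda_c' + \Lambda_e\Lambda_e'};
#' the cross-twin block drops E entirely and weights A by the kinship
#' coefficient (1 for MZ pairs, 0.5 for DZ pairs) while C is shared fully
#' by both zygosities.
#'
#' @param params An [ace_loadings] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric positive semi-definite `2d x 2d` matrix; twin 1's
#'   stages first, then twin 2's.
#' @examples
#' p <- ace_loadings(diag(1) * 0, diag(1) * 0, diag(1))
#' theoretical_pair_covariance(p, "MZ")  # identity: E-only twins are unrelated
#' @export
theoretical_pair_covariance <- function(params, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(params, "ace_loadings"))
  zygosity <- match.arg(zygosity)
  A <- tcrossprod(params$lambda_a)
  C <- tcrossprod(params$lambda_c)
  E <- tcrossprod(params$lambda_e)
  within <- A + C + E
  r_a <- if (zygosity == "MZ") 1 else 0.5
  cross <- r_a * A + C
  rbind(cbind(within, cross), cbind(cross, within))
}

#' Standardized variance-components table
#'
#' Squared loadings rescaled by the total phenotypic variance of each stage:
#' entry (stage i, factor j) is the proportion of stage i's variance
#' explained by factor j of each source. Per-stage totals are the row sums
#' per source; across sources the totals sum to one by construction.
#'
#' @param params An [ace_loadings] object.
#' @return An object of class `variance_components`: a list with 4 x 4 (or
#'   `d x d`) proportion matrices `A`, `C`, `E`, a `totals` matrix
#'   (stage x source), and `stage_variance`.
#' @export
standardize_components <- function(params) {
  stopifnot(inherits(params, "ace_loadings"))
  tv <- stage_variances(params)
  if (any(tv <= 0)) stop("zero total variance at stage ", which(tv <= 0)[1])
  comp <- list(A = params$lambda_a^2 / tv,
               C = params$lambda_c^2 / tv,
               E = params$lambda_e^2 / tv)
  d <- params$n_stages
  stages <- paste0("stage", seq_len(d))
  for (nm in names(comp)) {
    dimnames(comp[[nm]]) <- list(stages, paste0(nm, seq_len(d)))
  }
  totals <- cbind(A = rowSums(comp$A), C = rowSums(comp$C), E = rowSums(comp$E))
  rownames(totals) <- stages
  out <- c(comp, list(totals = totals, stage_variance = tv))
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, digits = 2, ...) {
  cat("Standardized variance components (proportions of stage variance)\n")
  for (nm in c("A", "C", "E")) {
    cat("\n", nm, " factors:\n", sep = "")
    print(round(x[[nm]], digits))
  }
  cat("\nTotals:\n")
  print(round(x$totals, digits))
  invisible(x)
}

#' Stage-specific (innovation) share of a variance source
#'
#' Of all the A, C or E variance acting on a given stage, the fraction
#' contributed by that stage's own factor -- influence newly arising at that
#' stage, independent of everything transmitted from earlier stages. For the
#' intervention stage this is the headline "innovation" statistic: the share
#' of (say) non-shared environmental influence specific to the intervention.
#'
#' @param components A `variance_components` object from
#'   [standardize_components()], or a plain lower-triangular matrix of
#'   per-stage contributions for one source.
#' @param source `"A"`, `"C"` or `"E"` (ignored when a matrix is supplied).
#' @param stage Stage index (1-based).
#' @return Proportion in \[0, 1\].
#' @examples
#' # E contributions at stage 3 of .22 (baseline factor), .06, .20 ->
#' # 42% of stage-3 E variance is intervention-specific
#' m <- matrix(0, 3, 3)
#' m[3, ] <- c(0.22, 0.06, 0.20)
#' stage_specific_proportion(m, stage = 3)
#' @export
stage_specific_proportion <- function(components, source = c("A", "C", "E"),
                                      stage) {
  if (inherits(components, "variance_components")) {
    source <- match.arg(source)
    m <- components[[source]]
  } else {
    m <- as.matrix(components)
  }
  stopifnot(stage >= 1, stage <= nrow(m))
  contrib <- m[stage, seq_len(stage)]
  denom <- sum(contrib)
  if (denom <= 0) stop("no variance from this source at stage ", stage)
  unname(contrib[stage] / denom)
}
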