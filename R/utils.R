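# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

is_lower_triangular <- function(m, tol = 0) {
  all(abs(m[upper.tri(m)]) <= tol)
}

# Lower-triangular Cholesky-type factor of a PSD matrix; eigenvalues are
# clipped at `ridge` so moment estimates that are slightly indefinite still
# yield usable starting values.
psd_lower_chol <- function(m, ridge = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, ridge)
  mm <- e$vectors %*% (vals * t(e$vectors))
  mm <- (mm + t(mm)) / 2
  t(chol(mm))
}

# "0.48 (.20-.64)" -- the conventional layout for standardized estimates
# with 95% confidence bounds.
fmt_est_ci <- function(est, lo, hi) {
  strip0 <- function(x) sub("^0\\.", ".", sprintf("%.2f", x))
  ifelse(is.na(lo) | is.na(hi),
         sprintf("%.2f", est),
         sprintf("%.2f (%s-%s)", est, strip0(lo), strip0(hi)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
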