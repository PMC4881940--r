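#' Questionnaire scale specifications
#'
#' The four outcome scales: the Subjective Happiness Scale (SHS; 4 items on
#' a 7-point scale, one reverse-keyed), the Brief Multidimensional Student
#' Life Satisfaction Scale (BMSLSS; 6 items, 7-point), the short Mood and
#' Feelings Questionnaire (MFQ; 13 items, 3-point) and the 6-item
#' State-Trait Anxiety Inventory (STAI6; 4-point). A scale score is the
#' mean of its items after un-reversing, and is missing unless at least
#' `min_nonmissing_fraction` of the items are present.
#'
#' @param name One of `"SHS"`, `"BMSLSS"`, `"MFQ"`, `"STAI6"`, or any name
#'   when the remaining arguments are supplied explicitly.
#' @param n_items,point_scale,reverse_items Override the built-in layout.
#' @param min_nonmissing_fraction Minimum fraction of non-missing items
#'   required for a score (default 0.5).
#' @return An object of class `scale_spec`.
#' @export
scale_spec <- function(name, n_items = NULL, point_scale = NULL,
                       reverse_items = NULL, min_nonmissing_fraction = 0.5) {
  builtin <- list(
    SHS    = list(n_items = 4L,  point_scale = 7L, reverse_items = 4L),
    BMSLSS = list(n_items = 6L,  point_scale = 7L, reverse_items = integer()),
    MFQ    = list(n_items = 13L, point_scale = 3L, reverse_items = integer()),
    STAI6  = list(n_items = 6L,  point_scale = 4L, reverse_items = integer()))
  if (is.null(n_items)) {
    if (!name %in% names(builtin)) {
      stop("unknown scale '", name, "'; known scales: ",
           paste(names(builtin), collapse = ", "))
    }
    b <- builtin[[name]]
    n_items <- b$n_items
    point_scale <- b$point_scale
    reverse_items <- b$reverse_items
  }
  reverse_items <- as.integer(reverse_items %||% integer())
  stopifnot(n_items >= 1, point_scale >= 2,
            all(reverse_items >= 1), all(reverse_items <= n_items),
            min_nonmissing_fraction > 0, min_nonmissing_fraction <= 1)
  out <- list(name = name, n_items = as.integer(n_items),
              point_scale = as.integer(point_scale),
              reverse_items = reverse_items,
              min_nonmissing_fraction = min_nonmissing_fraction)
  class(out) <- "scale_spec"
  out
}

# Equally spaced thresholds on the latent scale, symmetric about zero.
item_thresholds <- function(point_scale) {
  seq(-1.5, 1.5, length.out = point_scale - 1)
}

#' Simulate ordinal item responses from latent scores
#'
#' A graded-threshold measurement model: each item's latent value is
#' `loading * score + sqrt(1 - loading^2) * noise`, cut at equally spaced
#' thresholds into the scale's ordinal categories. Reverse-keyed items are
#' emitted flipped, so scoring (which un-reverses them) recovers a monotone
#' transform of the latent score. This is simulator scaffolding for testing
#' the scoring pipeline; it is not calibrated to any particular scale's
#' psychometrics.
#'
#' @param cohort A cohort `data.frame` with a `score` column on roughly a
#'   standard-normal latent scale.
#' @param spec A [scale_spec] (or scale name).
#' @param loading Correlation between the latent score and each item's
#'   latent value, in \[0, 1\].
#' @param seed Integer seed.
#' @return A long item-level `data.frame`: the cohort's identifier columns
#'   plus `scale`, `item`, `response`; missing latent scores give missing
#'   responses.
#' @export
simulate_items <- function(cohort, spec, loading = 0.85, seed = NULL) {
  if (is.character(spec)) spec <- scale_spec(spec)
  stopifnot(inherits(spec, "scale_spec"), loading >= 0, loading <= 1)
  with_seed(seed, {
    n <- nrow(cohort)
    m <- spec$n_items
    tau <- item_thresholds(spec$point_scale)
    id_cols <- intersect(c("family_id", "zygosity", "twin_index", "sex",
                           "age", "stage"), names(cohort))
    out <- cohort[rep(seq_len(n), each = m), id_cols, drop = FALSE]
    out$scale <- spec$name
    out$item <- rep.int(seq_len(m), n)
    latent <- rep(cohort$score, each = m)
    noise <- stats::rnorm(n * m)
    u <- loading * latent + sqrt(1 - loading^2) * noise
    resp <- 1L + rowSums(outer(u, tau, `>`))
    resp[is.na(latent)] <- NA_integer_
    rev <- out$item %in% spec$reverse_items
    resp[rev] <- spec$point_scale + 1L - resp[rev]
    out$response <- as.integer(resp)
    rownames(out) <- NULL
    out
  })
}

#' Score a scale from item responses
#'
#' Reverse-keyed items are mapped `v -> point_scale + 1 - v`, the score is
#' the mean of the present items, and the score is missing when fewer than
#' `min_nonmissing_fraction` of the items are present.
#'
#' @param item_responses A numeric vector (one observation) or matrix
#'   (observations x items) of responses in `1..point_scale` or `NA`.
#' @param spec A [scale_spec] (or scale name).
#' @return Numeric score(s), `NA` where too few items are present.
#' @examples
#' score_scale(c(7, 7, 7, 1), scale_spec("SHS"))  # reverse item 4 -> 7
#' @export
score_scale <- function(item_responses, spec) {
  if (is.character(spec)) spec <- scale_spec(spec)
  stopifnot(inherits(spec, "scale_spec"))
  x <- if (is.matrix(item_responses)) item_responses else
    matrix(item_responses, nrow = 1)
  if (ncol(x) != spec$n_items) {
    stop("expected ", spec$n_items, " items, got ", ncol(x))
  }
  bad <- !is.na(x) & (x < 1 | x > spec$point_scale | x != round(x))
  if (any(bad)) stop("responses must be integers in 1..", spec$point_scale)
  if (length(spec$reverse_items)) {
    x[, spec$reverse_items] <- spec$point_scale + 1 - x[, spec$reverse_items]
  }
  present <- rowMeans(!is.na(x))
  score <- rowMeans(x, na.rm = TRUE)
  score[present < spec$min_nonmissing_fraction] <- NA_real_
  score[is.nan(score)] <- NA_real_
  if (is.matrix(item_responses)) score else score[1]
}

#' Score a long item-level table back to one score per individual-stage
#'
#' @param items Long item-level `data.frame` from [simulate_items()].
#' @param spec A [scale_spec] (or scale name).
#' @return A cohort-shaped `data.frame` with a `score` column.
#' @export
score_item_cohort <- function(items, spec) {
  if (is.character(spec)) spec <- scale_spec(spec)
  key_cols <- intersect(c("family_id", "zygosity", "twin_index", "sex",
                          "age", "stage"), names(items))
  key <- do.call(paste, c(items[key_cols], sep = "\r"))
  ord <- order(key, items$item)
  items <- items[ord, ]
  key <- key[ord]
  first <- !duplicated(key)
  resp <- matrix(items$response, ncol = spec$n_items, byrow = TRUE)
  out <- items[first, key_cols, drop = FALSE]
  out$score <- score_scale(resp, spec)
  rownames(out) <- NULL
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' Utility for item-level data: `k/(k-1) * (1 - sum(item variances) /
#' variance of the total)`, computed on complete rows.
#'
#' @param responses Matrix of item responses (observations x items), after
#'   any reverse-keying.
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(responses) {
  x <- responses[stats::complete.cases(responses), , drop = FALSE]
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}
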