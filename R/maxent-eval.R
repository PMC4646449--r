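#' Map presence points to stack cell indices
#'
#' @param spec A [grid_spec()].
#' @param points Data frame with columns `x`, `y`.
#' @return Integer vector of column-major linear cell indices; points outside
#'   the grid are dropped with a warning.
#' @export
presence_cells <- function(spec, points) {
  rc <- points_to_cells(spec, points$x, points$y)
  bad <- is.na(rc$row)
  if (any(bad)) {
    rlang::warn(sprintf("%d presence point(s) fall outside the grid and were dropped", sum(bad)))
  }
  rc <- rc[!bad, ]
  rc$row + (rc$col - 1L) * spec$n_rows
}

#' Suitability thresholds from a baseline prediction
#'
#' Computes the four thresholds used to binarise suitability maps: the first
#' quartile, median and third quartile of the predicted values over all
#' non-nodata landscape cells of the baseline (unmodified) landscape
#' (linear-interpolation quantiles), and the threshold maximising
#' sensitivity + specificity over the distinct predicted values at presences
#' and background points.
#'
#' @param baseline_prediction A [continuous_grid()] of predictions for the
#'   original landscape.
#' @param presences Integer presence cell indices.
#' @param background Integer background cell indices.
#' @return An object of class `threshold_set` with elements `q1`, `median`,
#'   `q3`, `max_ss` and `max_ss_value` (the maximised sensitivity +
#'   specificity).
#' @export
suitability_thresholds <- function(baseline_prediction, presences, background) {
  vals <- baseline_prediction$values[!is.na(baseline_prediction$values)]
  if (length(unique(vals)) < 4) {
    rlang::warn("fewer than 4 distinct prediction values; thresholds are degenerate")
  }
  qs <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  pr <- baseline_prediction$values[presences]
  bg <- baseline_prediction$values[background]
  cand <- sort(unique(c(pr, bg)))
  ss <- vapply(cand, function(t) mean(pr >= t) + mean(bg < t), numeric(1))
  best <- max(cand[ss >= max(ss) - 1e-12]) # ties toward the more specific threshold
  structure(
    list(
      q1 = qs[1], median = qs[2], q3 = qs[3],
      max_ss = best, max_ss_value = max(ss)
    ),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> q1 = %.4g, median = %.4g, q3 = %.4g, max_ss = %.4g (sens+spec = %.3f)\n",
    x$q1, x$median, x$q3, x$max_ss, x$max_ss_value
  ))
  invisible(x)
}

#' Evaluate a suitability prediction with presence-background AUC and TSS
#'
#' Builds a composite evaluation set of the presence predictions plus
#' `n_background` seeded background predictions labelled absent. AUC is the
#' rank-based probability that a random presence outscores a random
#' background point (ties count one half); TSS is
#' sensitivity + specificity - 1 at the max-sensitivity-plus-specificity
#' threshold of the composite set.
#'
#' @param prediction A [continuous_grid()] of suitability values.
#' @param presences Integer presence cell indices.
#' @param n_background Number of background points to sample (default 1000).
#' @param seed RNG seed for the background sample.
#' @param background Optional explicit background cell indices; when given, no
#'   sampling happens and `n_background`/`seed` are ignored.
#' @return A tibble with columns `auc`, `tss`, `threshold`, `n_presences`,
#'   `n_background`.
#' @export
evaluate_model <- function(prediction, presences, n_background = 1000L, seed = 1L,
                           background = NULL) {
  if (length(presences) == 0) {
    rlang::abort("no presences to evaluate", class = "scenhab_error_parameter")
  }
  if (n_background < 1) {
    rlang::abort("n_background must be >= 1", class = "scenhab_error_parameter")
  }
  cells <- which(!is.na(prediction$values))
  bg_cells <- background %||% withr::with_seed(
    seed,
    sample(cells, min(n_background, length(cells)))
  )
  pr <- prediction$values[presences]
  bg <- prediction$values[bg_cells]
  auc <- auc_rank(pr, bg)
  cand <- sort(unique(c(pr, bg)))
  ss <- vapply(cand, function(t) mean(pr >= t) + mean(bg < t), numeric(1))
  thr <- max(cand[ss >= max(ss) - 1e-12])
  tibble::tibble(
    auc = auc, tss = max(ss) - 1, threshold = thr,
    n_presences = length(pr), n_background = length(bg)
  )
}

# Rank AUC with half-credit for ties.
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validated AUC of a maxent configuration
#'
#' Reporting utility: splits presences into `k` folds, refits on each
#' training split and scores the held-out presences against a seeded
#' background sample. The deployed model should still be fit on all
#' presences; this only characterises predictive performance.
#'
#' @inheritParams maxent_fit
#' @param k Number of folds (default 10).
#' @param n_background Evaluation background size per fold.
#' @param seed RNG seed for fold assignment and evaluation samples.
#' @return A tibble with one row per fold (`fold`, `auc`) plus the mean as
#'   attribute `mean_auc`.
#' @export
cv_maxent <- function(presences, background, stack, beta = 1,
                      features = feature_spec(), k = 10L,
                      n_background = 1000L, seed = 1L) {
  n <- length(presences)
  k <- min(k, n)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  res <- purrr::map_dfr(seq_len(k), function(i) {
    fit <- maxent_fit(presences[folds != i], background, stack,
      beta = beta, features = features
    )
    pred <- stats::predict(fit, stack, type = "raw")
    ev <- evaluate_model(pred, presences[folds == i],
      n_background = n_background, seed = seed + i
    )
    tibble::tibble(fold = i, auc = ev$auc)
  })
  attr(res, "mean_auc") <- mean(res$auc)
  res
}
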