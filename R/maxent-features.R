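#' Maxent feature specification
#'
#' Declares which feature classes expand each predictor of the suitability
#' model. Predictors are first rescaled to `[0, 1]` using their range over the
#' training background; features are then
#' \describe{
#'   \item{linear}{the scaled predictor `z` itself,}
#'   \item{quadratic}{`z^2`,}
#'   \item{hinge}{forward hinges `max(0, (z - k) / (1 - k))` with knots `k`
#'     at equally spaced quantiles of the training background, strictly
#'     inside the predictor's range.}
#' }
#' The default (linear + quadratic + hinge, 10 knots per predictor) mirrors
#' the automatic feature choice of reference maxent software for moderate
#' presence sample sizes; product features are deliberately omitted.
#'
#' @param classes Character subset of `c("linear", "quadratic", "hinge")`.
#' @param n_hinge_knots Hinge knots per predictor.
#' @return An object of class `feature_spec` (uncalibrated: normalisation
#'   bounds and knots are filled in from the training background at fit time
#'   by [calibrate_features()]).
#' @export
feature_spec <- function(classes = c("linear", "quadratic", "hinge"),
                         n_hinge_knots = 10L) {
  classes <- match.arg(classes, c("linear", "quadratic", "hinge"), several.ok = TRUE)
  if (length(classes) == 0) {
    rlang::abort("at least one feature class must be enabled",
      class = "scenhab_error_parameter"
    )
  }
  structure(
    list(
      classes = classes, n_hinge_knots = as.integer(n_hinge_knots),
      calibrated = FALSE
    ),
    class = "feature_spec"
  )
}

#' Calibrate a feature specification against training background predictors
#'
#' Computes per-predictor normalisation bounds (background min/max) and hinge
#' knot positions (equally spaced background quantiles). Predictors that are
#' constant over the background would yield only zero-variance features and
#' are dropped with a warning.
#'
#' @param predictors Numeric matrix (background cells x predictors) with
#'   column names.
#' @param spec A [feature_spec()].
#' @return The calibrated `feature_spec`: adds `bounds` (tibble), `features`
#'   (tibble with one row per feature: `feature`, `predictor`, `type`,
#'   `knot`).
#' @export
calibrate_features <- function(predictors, spec = feature_spec()) {
  stopifnot(is.matrix(predictors), !is.null(colnames(predictors)))
  lo <- apply(predictors, 2, min)
  hi <- apply(predictors, 2, max)
  constant <- hi <= lo
  if (any(constant)) {
    rlang::warn(sprintf(
      "dropping constant predictor(s): %s",
      paste(colnames(predictors)[constant], collapse = ", ")
    ))
  }
  keep <- colnames(predictors)[!constant]
  if (length(keep) == 0) {
    rlang::abort("no non-constant predictors", class = "scenhab_error_degenerate")
  }
  rows <- list()
  knots <- list()
  for (p in keep) {
    z <- (predictors[, p] - lo[p]) / (hi[p] - lo[p])
    if ("linear" %in% spec$classes) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = p, predictor = p, type = "linear", knot = NA_real_
      )
    }
    if ("quadratic" %in% spec$classes) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = paste0(p, "^2"), predictor = p, type = "quadratic", knot = NA_real_
      )
    }
    if ("hinge" %in% spec$classes && spec$n_hinge_knots > 0) {
      qs <- stats::quantile(z, probs = seq_len(spec$n_hinge_knots) / (spec$n_hinge_knots + 1),
        type = 7, names = FALSE
      )
      qs <- unique(qs[qs > 0 & qs < 1])
      if (length(qs) > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          feature = sprintf("hinge(%s,%.6g)", p, qs),
          predictor = p, type = "hinge", knot = qs
        )
      }
    }
  }
  spec$bounds <- tibble::tibble(predictor = keep, min = lo[keep], max = hi[keep])
  spec$features <- dplyr::bind_rows(rows)
  spec$calibrated <- TRUE
  spec
}

#' Build the maxent design matrix
#'
#' Evaluates every feature of a calibrated [feature_spec()] on a predictor
#' matrix. Values at the background extremes map to 0 and 1 for linear
#' features; cells outside the training range extrapolate linearly (no
#' clamping).
#'
#' @param predictors Numeric matrix (cells x predictors), columns named as at
#'   calibration.
#' @param spec A calibrated `feature_spec`.
#' @return Numeric matrix (cells x features) with feature names as columns.
#' @export
build_features <- function(predictors, spec) {
  if (!isTRUE(spec$calibrated)) {
    rlang::abort("feature_spec must be calibrated first", class = "scenhab_error_parameter")
  }
  missing <- setdiff(spec$bounds$predictor, colnames(predictors))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "predictor layers missing: %s", paste(missing, collapse = ", ")
    ), class = "scenhab_error_schema")
  }
  n <- nrow(predictors)
  out <- matrix(0, n, nrow(spec$features))
  colnames(out) <- spec$features$feature
  z <- list()
  for (i in seq_len(nrow(spec$bounds))) {
    b <- spec$bounds[i, ]
    z[[b$predictor]] <- (predictors[, b$predictor] - b$min) / (b$max - b$min)
  }
  for (j in seq_len(nrow(spec$features))) {
    f <- spec$features[j, ]
    zj <- z[[f$predictor]]
    out[, j] <- switch(f$type,
      linear = zj,
      quadratic = zj^2,
      hinge = pmax(0, (zj - f$knot) / (1 - f$knot))
    )
  }
  out
}
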