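#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a fitted maxent model into a coefficient table
#'
#' @param x A [maxent_fit()] model.
#' @param ... Unused.
#' @return One row per feature: `feature`, `predictor`, `type`, `knot`,
#'   `estimate` (lambda), `penalty_scale`.
#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  dplyr::mutate(x$feature_spec$features,
    estimate = unname(x$lambdas),
    penalty_scale = unname(x$s)
  )
}

#' One-row summary of a fitted maxent model
#'
#' @param x A [maxent_fit()] model.
#' @param ... Unused.
#' @return A tibble with `beta`, `log_likelihood`, `n_params`, `aicc`,
#'   `entropy`, `n_presences`, `background_size`, `converged`, `iterations`.
#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  K <- sum(x$lambdas != 0)
  tibble::tibble(
    beta = x$beta, log_likelihood = x$log_likelihood, n_params = K,
    aicc = suppressWarnings(aicc(x$log_likelihood, K, x$presence_count)),
    entropy = x$entropy, n_presences = x$presence_count,
    background_size = x$background_size,
    converged = x$converged, iterations = x$iterations
  )
}

#' @method tidy change_summary
#' @export
tidy.change_summary <- function(x, ...) x$classes

#' @method glance change_summary
#' @export
glance.change_summary <- function(x, ...) {
  tibble::tibble(
    seed = x$seed,
    total_converted_cells = if (is.null(x$rules)) NA_integer_ else sum(x$rules$converted_cells),
    n_rules = if (is.null(x$rules)) 0L else nrow(x$rules)
  )
}

#' @method tidy scenario_comparison
#' @export
tidy.scenario_comparison <- function(x, ...) x$pairwise

#' @method glance scenario_comparison
#' @export
glance.scenario_comparison <- function(x, ...) {
  dplyr::mutate(x$omnibus,
    threshold_name = x$threshold_name,
    baseline = if (is.null(x$baseline)) NA_real_ else x$baseline
  )
}

#' @method tidy threshold_set
#' @export
tidy.threshold_set <- function(x, ...) {
  tibble::tibble(
    threshold_name = c("q1", "median", "q3", "max_ss"),
    value = c(x$q1, x$median, x$q3, x$max_ss)
  )
}

#' Tidy a habitat grid into long cell records
#'
#' @param x A [habitat_grid()].
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `code`, `class`.
#' @method as_tibble habitat_grid
#' @export
as_tibble.habitat_grid <- function(x, ...) {
  nr <- x$spec$n_rows
  nc <- x$spec$n_cols
  code <- as.vector(x$classes)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    code = code,
    class = names(x$legend)[match(code, x$legend)]
  )
}

#' @method as_tibble continuous_grid
#' @export
as_tibble.continuous_grid <- function(x, ...) {
  nr <- x$spec$n_rows
  nc <- x$spec$n_cols
  out <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr)
  )
  out[[x$name]] <- as.vector(x$values)
  out
}
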