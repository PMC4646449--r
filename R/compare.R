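#' Proportion of the landscape predicted suitable
#'
#' Fraction of non-nodata cells whose predicted suitability meets or exceeds
#' the threshold (cells exactly at the threshold count as suitable).
#'
#' @param prediction A [continuous_grid()] of suitability values.
#' @param threshold Suitability threshold.
#' @return A proportion in `[0, 1]`.
#' @export
suitable_proportion <- function(prediction, threshold) {
  vals <- prediction$values[!is.na(prediction$values)]
  if (length(vals) == 0) {
    rlang::abort("prediction grid is all nodata", class = "scenhab_error_parameter")
  }
  mean(vals >= threshold)
}

#' Kruskal-Wallis rank test across scenario ensembles
#'
#' Omnibus test for a difference in location among two or more groups. H is
#' tie-corrected; p comes from the chi-squared distribution with k - 1
#' degrees of freedom. If every value is identical, H = 0 and p = 1.
#'
#' @param groups Named list of numeric samples.
#' @return A one-row tibble: `statistic` ("H"), `value`, `df`, `p_value`,
#'   `group_sizes` (list-column).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    rlang::abort("need >= 2 nonempty groups", class = "scenhab_error_parameter")
  }
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1) {
    h <- 0
    p <- 1
    df <- length(groups) - 1
  } else {
    kt <- stats::kruskal.test(groups)
    h <- unname(kt$statistic)
    p <- kt$p.value
    df <- unname(kt$parameter)
  }
  tibble::tibble(
    statistic = "H", value = h, df = df, p_value = p,
    group_sizes = list(lengths(groups))
  )
}

#' Mann-Whitney U test between two ensembles
#'
#' Reports U as the smaller of the two one-sided U statistics and a two-sided
#' p-value: exact when both samples have at most 8 observations and no ties,
#' otherwise the normal approximation with tie correction.
#'
#' @param a,b Numeric samples.
#' @return A one-row tibble: `statistic` ("U"), `value`, `n_a`, `n_b`,
#'   `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    rlang::abort("both samples must be nonempty", class = "scenhab_error_parameter")
  }
  m <- length(a)
  n <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- m <= 8 && n <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  u_a <- unname(wt$statistic)
  u <- min(u_a, m * n - u_a)
  p <- wt$p.value
  if (is.nan(p)) p <- 1 # fully tied data: no evidence of a difference
  tibble::tibble(statistic = "U", value = u, n_a = m, n_b = n, p_value = p)
}

#' Compare suitable-area proportions across scenario ensembles
#'
#' Takes per-run suitable-area records, selects one threshold, and reports:
#' the omnibus Kruskal-Wallis test across scenarios, all pairwise
#' Mann-Whitney tests, each scenario against its matched null ensemble
#' (scenarios named `<scenario>_null`), and per-scenario medians alongside
#' the baseline proportion. No multiple-testing correction is applied unless
#' `holm = TRUE`.
#'
#' @param records Tibble with columns `scenario`, `run`, `threshold_name`,
#'   `proportion_suitable` (see [project_ensembles()]).
#' @param threshold_name One of the threshold names present in `records`.
#' @param baseline Suitable proportion of the unmodified landscape at this
#'   threshold (the dotted-line value), or NULL.
#' @param holm Apply Holm correction to the pairwise p-values.
#' @return An object of class `scenario_comparison`: tibbles `omnibus`,
#'   `pairwise`, `vs_null`, `medians`, plus `baseline` and `threshold_name`.
#' @export
compare_scenarios <- function(records, threshold_name, baseline = NULL, holm = FALSE) {
  recs <- records[records$threshold_name == threshold_name, ]
  if (nrow(recs) == 0) {
    rlang::abort("no records at that threshold", class = "scenhab_error_parameter")
  }
  all_names <- sort(unique(recs$scenario))
  nulls <- all_names[grepl("_null$", all_names)]
  actual <- setdiff(all_names, nulls)
  if (length(actual) < 2) {
    rlang::abort("need >= 2 scenarios to compare", class = "scenhab_error_parameter")
  }
  by_scn <- lapply(all_names, function(s) recs$proportion_suitable[recs$scenario == s])
  names(by_scn) <- all_names
  if (any(lengths(by_scn[actual]) < 2)) {
    rlang::abort("each scenario needs >= 2 runs", class = "scenhab_error_parameter")
  }
  omnibus <- kruskal_wallis(by_scn[actual])
  pairs <- utils::combn(actual, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    res <- mann_whitney(by_scn[[pairs[1, i]]], by_scn[[pairs[2, i]]])
    dplyr::mutate(res, scenario_a = pairs[1, i], scenario_b = pairs[2, i], .before = 1)
  })
  if (holm) pairwise$p_value <- stats::p.adjust(pairwise$p_value, method = "holm")
  vs_null <- purrr::map_dfr(actual, function(s) {
    nul <- paste0(s, "_null")
    if (!nul %in% nulls) {
      rlang::warn(sprintf("no null ensemble for scenario '%s'; comparison skipped", s))
      return(NULL)
    }
    res <- mann_whitney(by_scn[[s]], by_scn[[nul]])
    dplyr::mutate(res, scenario = s, .before = 1)
  })
  medians <- tibble::tibble(
    scenario = all_names,
    median = vapply(by_scn, stats::median, numeric(1)),
    n_runs = lengths(by_scn)
  )
  structure(
    list(
      omnibus = omnibus, pairwise = pairwise, vs_null = vs_null,
      medians = medians, baseline = baseline, threshold_name = threshold_name
    ),
    class = "scenario_comparison"
  )
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf(
    "<scenario_comparison> threshold '%s'%s\n", x$threshold_name,
    if (!is.null(x$baseline)) sprintf(", baseline proportion %.4f", x$baseline) else ""
  ))
  cat(sprintf(
    "omnibus Kruskal-Wallis: H = %.3f, df = %d, p = %.3g\n",
    x$omnibus$value, x$omnibus$df, x$omnibus$p_value
  ))
  cat("medians:\n")
  print(x$medians)
  cat("pairwise Mann-Whitney:\n")
  print(x$pairwise)
  if (!is.null(x$vs_null) && nrow(x$vs_null) > 0) {
    cat("scenario vs null:\n")
    print(x$vs_null)
  }
  invisible(x)
}
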