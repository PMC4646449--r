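#' Label connected patches of a habitat class
#'
#' Connected components of target-class cells under 4- or 8-neighbour
#' connectivity, labelled `1..np`.
#'
#' @param grid A [habitat_grid()].
#' @param target_class Class name or code.
#' @param connectivity 4 or 8 (default 8, matching the growth engine).
#' @return A list with `labels` (integer matrix, NA outside the class) and
#'   `np` (number of patches; 0 if the class is absent).
#' @export
label_patches <- function(grid, target_class, connectivity = 8L) {
  code <- resolve_class(grid$legend, target_class)
  is_t <- !is.na(grid$classes) & grid$classes == code
  nr <- nrow(is_t)
  nc <- ncol(is_t)
  cells <- which(is_t)
  labels <- matrix(NA_integer_, nr, nc)
  if (length(cells) == 0) {
    return(list(labels = labels, np = 0L))
  }
  # edges between adjacent target cells; components via igraph
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8L) offs <- c(offs, list(c(1, 1), c(1, -1)))
  edges <- list()
  idx <- matrix(0L, nr, nc)
  idx[cells] <- seq_along(cells)
  rc_row <- ((cells - 1L) %% nr) + 1L
  rc_col <- ((cells - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- rc_row + o[1]
    c2 <- rc_col + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- is_t[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      edges[[length(edges) + 1]] <- cbind(
        idx[cells[ok]],
        idx[cbind(r2[ok], c2[ok])]
      )
    }
  }
  em <- do.call(rbind, c(list(matrix(0L, 0, 2)), edges))
  g <- igraph::make_graph(as.vector(t(em)), n = length(cells), directed = FALSE)
  comp <- igraph::components(g)
  labels[cells] <- comp$membership
  list(labels = labels, np = comp$no)
}

#' Patch metrics for a habitat class
#'
#' Computes the patch-level landscape metrics used to characterise
#' before/after forestry change: number of patches (NP), total edge (TE, km),
#' total area (TA, km2) and mean patch area (MA, km2). Edge counts every cell
#' face between a target cell and a non-target cell; faces on the map
#' boundary count too (the outside is treated as non-target) unless
#' `boundary_edge = FALSE`.
#'
#' @inheritParams label_patches
#' @param boundary_edge Count map-boundary faces toward TE (default TRUE).
#' @return A one-row tibble: `class`, `np`, `te_km`, `ta_km2`, `ma_km2`,
#'   `empty` (TRUE when the class is absent, in which case `ma_km2` is
#'   reported as 0).
#' @export
patch_metrics <- function(grid, target_class, connectivity = 8L, boundary_edge = TRUE) {
  code <- resolve_class(grid$legend, target_class)
  cls_name <- if (is.character(target_class)) {
    target_class
  } else {
    names(grid$legend)[match(code, grid$legend)]
  }
  is_t <- !is.na(grid$classes) & grid$classes == code
  n_cells <- sum(is_t)
  cell <- grid$spec$cell_size
  lab <- label_patches(grid, target_class, connectivity)
  if (n_cells == 0) {
    return(tibble::tibble(
      class = cls_name, np = 0L, te_km = 0, ta_km2 = 0, ma_km2 = 0, empty = TRUE
    ))
  }
  nr <- nrow(is_t)
  nc <- ncol(is_t)
  faces <- 0L
  # vertical neighbours
  faces <- faces + sum(is_t[-nr, ] != is_t[-1, ])
  # horizontal neighbours
  faces <- faces + sum(is_t[, -nc] != is_t[, -1])
  if (boundary_edge) {
    faces <- faces + sum(is_t[1, ]) + sum(is_t[nr, ]) + sum(is_t[, 1]) + sum(is_t[, nc])
  }
  ta <- n_cells * cell^2 / 1e6
  tibble::tibble(
    class = cls_name, np = lab$np,
    te_km = faces * cell / 1e3,
    ta_km2 = ta, ma_km2 = ta / lab$np, empty = FALSE
  )
}

#' Patch metrics across an ensemble
#'
#' Convenience wrapper: metrics of one class for the baseline grid and every
#' run of a [run_ensemble()] result, ready for before/after comparison.
#'
#' @param baseline Baseline [habitat_grid()].
#' @param ensemble Tibble from [run_ensemble()].
#' @param target_class Class name or code.
#' @param connectivity 4 or 8.
#' @return A tibble with columns `scenario`, `run` (0 = baseline) and the
#'   [patch_metrics()] columns.
#' @export
ensemble_patch_metrics <- function(baseline, ensemble, target_class, connectivity = 8L) {
  base <- dplyr::mutate(
    patch_metrics(baseline, target_class, connectivity),
    scenario = "baseline", run = 0L, .before = 1
  )
  rest <- purrr::map2_dfr(ensemble$grid, seq_len(nrow(ensemble)), function(g, i) {
    dplyr::mutate(
      patch_metrics(g, target_class, connectivity),
      scenario = ensemble$scenario[i], run = ensemble$run[i], .before = 1
    )
  })
  dplyr::bind_rows(base, rest)
}
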