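#' Grid georeferencing specification
#'
#' Describes the shape and georeferencing of a raster grid: dimensions, square
#' cell size in metres, map coordinates of the upper-left corner, an opaque
#' CRS identifier and the integer code used for nodata in files. All grids
#' combined in one analysis must share an identical `grid_spec`.
#'
#' Cells are half-open: a point (x, y) falls in the cell whose extent is
#' `[x0 + (j-1) cell, x0 + j cell)` horizontally and analogously from the top
#' downwards. Row 1, column 1 is the upper-left cell.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2: map (x, y) of the upper-left corner.
#' @param crs_id Opaque CRS string, recorded but never interpreted.
#' @param nodata_code Integer code written for nodata cells in files.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, origin = c(0, n_rows * cell_size),
                      crs_id = "local", nodata_code = -9999L) {
  if (n_rows < 1 || n_cols < 1) {
    rlang::abort("n_rows and n_cols must be >= 1", class = "scenhab_error_parameter")
  }
  if (cell_size <= 0) {
    rlang::abort("cell_size must be > 0", class = "scenhab_error_parameter")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = as.numeric(cell_size), origin = as.numeric(origin),
      crs_id = as.character(crs_id), nodata_code = as.integer(nodata_code)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells, %.6g m resolution, origin (%.6g, %.6g), crs '%s'\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2], x$crs_id
  ))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d @ %gm", x$n_rows, x$n_cols, x$cell_size)
}

same_spec <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_same_spec <- function(a, b, what = "grids") {
  if (!same_spec(a, b)) {
    rlang::abort(paste0("all ", what, " in one analysis must share the same grid_spec"),
      class = "scenhab_error_schema"
    )
  }
}

#' Categorical habitat raster
#'
#' A categorical raster of habitat classes: an integer matrix of class codes
#' (NA for nodata) plus a legend mapping each code to a class name.
#'
#' @param classes Integer matrix of class codes; NA marks nodata.
#' @param spec A [grid_spec()] matching `dim(classes)`.
#' @param legend Named integer vector or named list: `name = code`. Every
#'   non-nodata code in `classes` must appear in the legend.
#' @return An object of class `habitat_grid`.
#' @export
habitat_grid <- function(classes, spec, legend) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  if (nrow(classes) != spec$n_rows || ncol(classes) != spec$n_cols) {
    rlang::abort("classes matrix does not match spec dimensions",
      class = "scenhab_error_schema"
    )
  }
  legend <- unlist(legend)
  legend <- stats::setNames(as.integer(legend), names(legend))
  if (any(legend < 0)) {
    rlang::abort("class codes must be nonnegative integers", class = "scenhab_error_parameter")
  }
  present <- unique(classes[!is.na(classes)])
  if (!all(present %in% legend)) {
    rlang::abort(
      sprintf(
        "codes present in grid but missing from legend: %s",
        paste(setdiff(present, legend), collapse = ", ")
      ),
      class = "scenhab_error_schema"
    )
  }
  structure(list(spec = spec, classes = classes, legend = legend),
    class = "habitat_grid"
  )
}

#' @export
print.habitat_grid <- function(x, ...) {
  cat(sprintf(
    "<habitat_grid> %s, %d classes (%s)\n", format(x$spec),
    length(x$legend), paste(names(x$legend), collapse = ", ")
  ))
  invisible(x)
}

#' Continuous raster layer
#'
#' @param values Numeric matrix; NA marks nodata; all non-NA values must be
#'   finite.
#' @param spec A [grid_spec()] matching `dim(values)`.
#' @param name Layer name.
#' @return An object of class `continuous_grid`.
#' @export
continuous_grid <- function(values, spec, name = "layer") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
    rlang::abort("values matrix does not match spec dimensions",
      class = "scenhab_error_schema"
    )
  }
  if (any(!is.finite(values) & !is.na(values))) {
    rlang::abort("non-finite values at non-nodata cells", class = "scenhab_error_parameter")
  }
  structure(list(spec = spec, values = values, name = name),
    class = "continuous_grid"
  )
}

#' @export
print.continuous_grid <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "<continuous_grid> '%s' %s, range [%.4g, %.4g]\n",
    x$name, format(x$spec), rng[1], rng[2]
  ))
  invisible(x)
}

#' Per-class cell counts of a habitat grid
#'
#' @param grid A [habitat_grid()].
#' @return A tibble with columns `class` (name), `code`, `cells` and `area_km2`.
#' @export
class_areas <- function(grid) {
  counts <- vapply(
    grid$legend,
    function(code) sum(grid$classes == code, na.rm = TRUE),
    integer(1)
  )
  tibble::tibble(
    class = names(grid$legend),
    code = unname(grid$legend),
    cells = unname(counts),
    area_km2 = unname(counts) * grid$spec$cell_size^2 / 1e6
  )
}

#' Map coordinates of cell centres
#'
#' @param spec A [grid_spec()].
#' @param rows,cols Row and column indices (1-based, row 1 at the top).
#' @return A tibble with columns `x`, `y`.
#' @export
cell_centers <- function(spec, rows, cols) {
  tibble::tibble(
    x = spec$origin[1] + (cols - 0.5) * spec$cell_size,
    y = spec$origin[2] - (rows - 0.5) * spec$cell_size
  )
}

#' Cell indices of map points
#'
#' Points are assigned by the half-open cell convention; points outside the
#' grid get NA row/col.
#'
#' @param spec A [grid_spec()].
#' @param x,y Map coordinates.
#' @return A tibble with columns `row`, `col`.
#' @export
points_to_cells <- function(spec, x, y) {
  col <- floor((x - spec$origin[1]) / spec$cell_size) + 1
  row <- floor((spec$origin[2] - y) / spec$cell_size) + 1
  # points exactly on the top/left boundary belong to the first cell;
  # the bottom/right boundary is outside (half-open cells)
  bad <- row < 1 | row > spec$n_rows | col < 1 | col > spec$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}
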