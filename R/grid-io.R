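#' Read and write rasters as ESRI ASCII grids
#'
#' `scenhab`'s native raster format is the ESRI ASCII grid (`.asc`): a
#' six-line plain-text header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of values from the top of the
#' map down. Habitat grids additionally carry a JSON sidecar
#' (`<path>.json`) with the legend (`{"name": code, ...}`) and CRS string.
#'
#' @param path Path to the `.asc` file. For habitat grids the legend sidecar
#'   is `paste0(path, ".json")` unless `legend` is supplied.
#' @param grid The grid to write.
#' @param legend Optional legend (named code vector) overriding the sidecar.
#' @param crs_id CRS string recorded in the sidecar.
#' @return `read_habitat_grid()` a [habitat_grid()]; `read_continuous_grid()` a
#'   [continuous_grid()]; the writers return `path` invisibly.
#' @name raster_io
NULL

parse_asc_header <- function(lines) {
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  required <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(required %in% names(hdr))) {
    rlang::abort("missing geotransform header fields in ASCII grid",
      class = "scenhab_error_format"
    )
  }
  if (is.null(hdr$nodata_value)) hdr$nodata_value <- -9999
  hdr
}

read_asc_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- parse_asc_header(lines)
  body <- paste(lines[-(1:6)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  if (length(vals) != hdr$nrows * hdr$ncols) {
    rlang::abort("ASCII grid body does not match declared dimensions",
      class = "scenhab_error_format"
    )
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  list(header = hdr, values = m)
}

write_asc_matrix <- function(m, spec, path, digits = NULL) {
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin[1]),
    sprintf("yllcorner %.10g", spec$origin[2] - spec$n_rows * spec$cell_size),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %d", spec$nodata_code)
  )
  m[is.na(m)] <- spec$nodata_code
  rows <- apply(m, 1, function(r) {
    paste(
      if (is.null(digits)) format(r, trim = TRUE, scientific = FALSE) else
        formatC(r, digits = digits, format = "g"),
      collapse = " "
    )
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}

spec_from_header <- function(hdr, crs_id = "local", nodata_code = -9999L) {
  grid_spec(
    n_rows = hdr$nrows, n_cols = hdr$ncols, cell_size = hdr$cellsize,
    origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
    crs_id = crs_id,
    nodata_code = as.integer(if (is.null(hdr$nodata_value)) nodata_code else hdr$nodata_value)
  )
}

#' @rdname raster_io
#' @export
read_habitat_grid <- function(path, legend = NULL) {
  parsed <- read_asc_matrix(path)
  vals <- parsed$values
  ok <- is.na(vals) | (is.finite(vals) & vals == round(vals))
  if (!all(ok)) {
    rlang::abort("habitat grid band contains non-integer values",
      class = "scenhab_error_format"
    )
  }
  crs_id <- "local"
  sidecar <- paste0(path, ".json")
  if (is.null(legend)) {
    if (!file.exists(sidecar)) {
      rlang::abort(paste0("no legend supplied and no sidecar found at ", sidecar),
        class = "scenhab_error_format"
      )
    }
    meta <- jsonlite::read_json(sidecar)
    legend <- unlist(meta$legend)
    if (!is.null(meta$crs_id)) crs_id <- meta$crs_id
  }
  spec <- spec_from_header(parsed$header, crs_id = crs_id)
  habitat_grid(vals, spec, legend)
}

#' @rdname raster_io
#' @export
write_habitat_grid <- function(grid, path) {
  write_asc_matrix(grid$classes, grid$spec, path)
  jsonlite::write_json(
    list(legend = as.list(grid$legend), crs_id = grid$spec$crs_id),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname raster_io
#' @export
read_continuous_grid <- function(path, name = NULL) {
  parsed <- read_asc_matrix(path)
  if (is.null(name)) name <- sub("\\.asc$", "", basename(path))
  continuous_grid(parsed$values, spec_from_header(parsed$header), name = name)
}

#' @rdname raster_io
#' @export
write_continuous_grid <- function(grid, path) {
  write_asc_matrix(grid$values, grid$spec, path, digits = 10)
  invisible(path)
}

#' Read and write presence points
#'
#' Presence locations are a CSV with columns `x`, `y` in the raster's map
#' coordinates.
#'
#' @param path CSV path.
#' @param points A data frame with columns `x` and `y`.
#' @return `read_presences()` a tibble with columns `x`, `y`.
#' @export
read_presences <- function(path) {
  pts <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x", "y") %in% names(pts))) {
    rlang::abort("presence CSV must have columns x and y", class = "scenhab_error_format")
  }
  tibble::as_tibble(pts[, c("x", "y")])
}

#' @rdname read_presences
#' @export
write_presences <- function(points, path) {
  readr::write_csv(points[, c("x", "y")], path)
  invisible(path)
}
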