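#' Circular focal-window kernel
#'
#' Binary mask of the cell offsets within a Euclidean radius of a focal cell.
#' An offset (di, dj) is included iff (di * cell_size)^2 + (dj * cell_size)^2
#' <= radius^2, so the centre cell is always included and the mask has odd
#' side length `2 * floor(radius / cell_size) + 1`.
#'
#' @param radius Window radius in metres (>= cell_size / 2).
#' @param cell_size Cell edge length in metres.
#' @return A 0/1 matrix of odd dimensions.
#' @export
circular_kernel <- function(radius, cell_size) {
  if (radius < cell_size / 2) {
    rlang::abort("radius must be at least half a cell", class = "scenhab_error_parameter")
  }
  r_cells <- floor(radius / cell_size)
  offs <- -r_cells:r_cells
  d2 <- outer(offs^2, offs^2, "+") * cell_size^2
  mask <- (d2 <= radius^2) * 1
  mask
}

# 2-D "same" convolution with zero padding via FFT. Kernel must have odd
# dimensions. Used for window counting: inputs are 0/1 indicators, so the
# result is rounded back to exact integer counts.
conv2_count <- function(x, kernel) {
  nr <- nrow(x)
  nc <- ncol(x)
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  pr <- nr + kr - 1
  pc <- nc + kc - 1
  xp <- matrix(0, pr, pc)
  xp[1:nr, 1:nc] <- x
  kp <- matrix(0, pr, pc)
  kp[1:kr, 1:kc] <- kernel
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / (pr * pc)
  ro <- (kr - 1) / 2
  co <- (kc - 1) / 2
  round(full[(ro + 1):(ro + nr), (co + 1):(co + nc)])
}

#' Focal class proportions
#'
#' For every cell, the proportion of each habitat class among the in-grid,
#' non-nodata cells inside a circular window centred on that cell. Window
#' counts are normalised by the number of available window cells, so
#' proportions sum to 1 at map edges too. Optional continuous covariate
#' layers are appended unchanged.
#'
#' @param grid A [habitat_grid()].
#' @param radius Window radius in metres; default 2000 m, a conservative
#'   year-round territory radius for black grouse.
#' @param covariates List of [continuous_grid()] covariates sharing the grid's
#'   spec (e.g. altitude).
#' @return A `focal_stack`: layers named after the legend classes (proportion
#'   layers, in `[0, 1]`) plus one layer per covariate.
#' @export
focal_proportions <- function(grid, radius = 2000, covariates = list()) {
  spec <- grid$spec
  if (length(grid$legend) == 0) {
    rlang::abort("legend is empty", class = "scenhab_error_parameter")
  }
  if (radius < spec$cell_size) {
    rlang::abort("radius must be at least one cell", class = "scenhab_error_parameter")
  }
  kernel <- circular_kernel(radius, spec$cell_size)
  valid <- !is.na(grid$classes)
  avail <- conv2_count(valid * 1, kernel)
  layers <- list()
  for (i in seq_along(grid$legend)) {
    code <- grid$legend[i]
    ind <- (valid & grid$classes == code) * 1
    prop <- conv2_count(ind, kernel) / pmax(avail, 1)
    prop[avail == 0 | !valid] <- NA
    layers[[names(grid$legend)[i]]] <- prop
  }
  for (cov in covariates) {
    stopifnot_same_spec(spec, cov$spec, "covariate grids")
    layers[[cov$name]] <- cov$values
  }
  focal_stack(layers,
    spec = spec, radius = radius,
    class_layers = names(grid$legend)
  )
}

#' Focal predictor stack
#'
#' An ordered set of continuous layers over a shared grid: one focal
#' class-proportion layer per habitat class plus optional covariates. This is
#' the predictor space of the suitability model.
#'
#' @param layers Named list of numeric matrices.
#' @param spec Shared [grid_spec()].
#' @param radius Focal window radius (m) used to build the proportion layers.
#' @param class_layers Names of the layers that are class proportions.
#' @return An object of class `focal_stack`.
#' @export
focal_stack <- function(layers, spec, radius, class_layers = names(layers)) {
  for (l in layers) {
    if (nrow(l) != spec$n_rows || ncol(l) != spec$n_cols) {
      rlang::abort("all layers must match the spec dimensions", class = "scenhab_error_schema")
    }
  }
  structure(
    list(
      spec = spec, layers = layers, radius = radius,
      class_layers = class_layers
    ),
    class = "focal_stack"
  )
}

#' @export
print.focal_stack <- function(x, ...) {
  cat(sprintf(
    "<focal_stack> %s, radius %g m, layers: %s\n",
    format(x$spec), x$radius, paste(names(x$layers), collapse = ", ")
  ))
  invisible(x)
}

# Cells (linear indices, column-major) with no NA in any layer.
stack_defined_cells <- function(stack) {
  ok <- Reduce(`&`, lapply(stack$layers, function(l) !is.na(l)))
  which(ok)
}

# Predictor matrix (cells x layers) at the given linear cell indices.
stack_matrix <- function(stack, cells) {
  m <- vapply(stack$layers, function(l) l[cells], numeric(length(cells)))
  if (length(cells) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  colnames(m) <- names(stack$layers)
  m
}

#' Tidy a focal stack into a cell-by-layer tibble
#'
#' @param x A `focal_stack`.
#' @param ... Unused.
#' @return A tibble with `row`, `col` and one column per layer.
#' @method as_tibble focal_stack
#' @export
as_tibble.focal_stack <- function(x, ...) {
  nr <- x$spec$n_rows
  nc <- x$spec$n_cols
  out <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr)
  )
  for (nm in names(x$layers)) out[[nm]] <- as.vector(x$layers[[nm]])
  out
}
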