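#' Multiband continuous image
#'
#' @param bands Named list of numeric matrices sharing one [grid_spec()];
#'   NA marks nodata (a cell is defined only where every band is defined).
#' @param spec The shared [grid_spec()].
#' @return An object of class `multiband_image`.
#' @export
multiband_image <- function(bands, spec) {
  if (length(bands) < 1) {
    rlang::abort("an image needs at least one band", class = "scenhab_error_parameter")
  }
  if (is.null(names(bands))) names(bands) <- paste0("band_", seq_along(bands))
  for (b in bands) {
    if (nrow(b) != spec$n_rows || ncol(b) != spec$n_cols) {
      rlang::abort("all bands must match the spec dimensions", class = "scenhab_error_schema")
    }
  }
  structure(list(spec = spec, bands = bands), class = "multiband_image")
}

#' @export
print.multiband_image <- function(x, ...) {
  cat(sprintf(
    "<multiband_image> %s, %d bands (%s)\n", format(x$spec),
    length(x$bands), paste(names(x$bands), collapse = ", ")
  ))
  invisible(x)
}

image_defined_cells <- function(image) {
  ok <- Reduce(`&`, lapply(image$bands, function(b) !is.na(b)))
  which(ok)
}

image_matrix <- function(image, cells) {
  m <- vapply(image$bands, function(b) b[cells], numeric(length(cells)))
  colnames(m) <- names(image$bands)
  m
}

#' Principal-component reduction of a multiband image
#'
#' Combines correlated spectral bands into a smaller number of orthogonal
#' component-score bands. Components come from the eigendecomposition of the
#' band correlation matrix (bands are standardised first, since spectral
#' bands have heterogeneous scales) over non-nodata cells, ordered by
#' decreasing explained variance. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making the output deterministic.
#'
#' @param image A [multiband_image()] with at least 2 bands.
#' @param n_components Number of leading components to keep.
#' @return A [multiband_image()] of score bands `PC1..PCn`, with attributes
#'   `explained_variance` (proportions) and `loadings`.
#' @export
pca_reduce <- function(image, n_components) {
  if (length(image$bands) < 2) {
    rlang::abort("need at least 2 bands", class = "scenhab_error_parameter")
  }
  if (n_components < 1 || n_components > length(image$bands)) {
    rlang::abort("n_components must be between 1 and the number of bands",
      class = "scenhab_error_parameter"
    )
  }
  cells <- image_defined_cells(image)
  X <- image_matrix(image, cells)
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) {
    rlang::abort("all bands are constant; PCA is undefined",
      class = "scenhab_error_degenerate"
    )
  }
  mus <- colMeans(X)
  Z <- sweep(X, 2, mus)
  nz <- sds > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sds[nz], "/")
  C <- stats::cov(Z)
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  scores <- Z %*% V
  bands <- lapply(seq_len(n_components), function(j) {
    m <- matrix(NA_real_, image$spec$n_rows, image$spec$n_cols)
    m[cells] <- scores[, j]
    m
  })
  names(bands) <- paste0("PC", seq_len(n_components))
  out <- multiband_image(bands, image$spec)
  attr(out, "explained_variance") <- eig$values / sum(eig$values)
  attr(out, "loadings") <- V
  out
}

# k-means++ seeding: spread initial centres by distance-weighted sampling.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (i in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      centers[i, ] <- X[sample.int(n, 1), ]
    } else {
      centers[i, ] <- X[sample.int(n, 1, prob = d2), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[i, ])^2))
    }
  }
  centers
}

#' Unsupervised k-means classification of an image
#'
#' Assigns every non-nodata pixel to the nearest of `k` centroids in band
#' space (Euclidean distance), iterating assignment and centroid update until
#' assignments stabilise. Each of `n_init` restarts is seeded by k-means++
#' and the restart with the lowest within-cluster sum of squares wins;
#' the result is deterministic given `seed`.
#'
#' @param image A [multiband_image()] (typically PCA scores).
#' @param k Number of clusters (>= 2); must not exceed the number of distinct
#'   pixel vectors.
#' @param seed Integer RNG seed.
#' @param n_init Number of k-means++ restarts.
#' @param max_iter Iteration cap per restart.
#' @return A [habitat_grid()] with codes `1..k` and legend
#'   `cluster_1..cluster_k`; attributes `withinss` (total within-cluster sum
#'   of squares) and `centers`.
#' @export
kmeans_classify <- function(image, k, seed = 1L, n_init = 10L, max_iter = 100L) {
  if (k < 2) rlang::abort("k must be >= 2", class = "scenhab_error_parameter")
  cells <- image_defined_cells(image)
  X <- image_matrix(image, cells)
  n_distinct <- nrow(unique(X))
  if (k > n_distinct) {
    rlang::abort("k exceeds the number of distinct pixel vectors",
      class = "scenhab_error_parameter"
    )
  }
  best <- NULL
  withr::with_seed(seed, {
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_centers(X, k)
      km <- suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = max_iter, algorithm = "Lloyd")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  classes <- matrix(NA_integer_, image$spec$n_rows, image$spec$n_cols)
  classes[cells] <- best$cluster
  legend <- stats::setNames(seq_len(k), paste0("cluster_", seq_len(k)))
  out <- habitat_grid(classes, image$spec, legend)
  attr(out, "withinss") <- best$tot.withinss
  attr(out, "centers") <- best$centers
  out
}

#' Pooling map from raw clusters to broad habitat classes
#'
#' @param mapping Named vector: names are raw cluster codes (as character),
#'   values are pooled class codes. Must cover every raw code in the grid it
#'   is applied to.
#' @param pooled_legend Named vector `name = code` for the pooled classes.
#' @return An object of class `pooling_map`.
#' @export
pooling_map <- function(mapping, pooled_legend) {
  mapping <- stats::setNames(as.integer(mapping), names(mapping))
  pooled_legend <- stats::setNames(as.integer(unlist(pooled_legend)), names(pooled_legend))
  if (!all(mapping %in% pooled_legend)) {
    rlang::abort("every pooled code must appear in pooled_legend",
      class = "scenhab_error_mapping"
    )
  }
  structure(list(mapping = mapping, pooled_legend = pooled_legend),
    class = "pooling_map"
  )
}

#' Read/write a pooling map as JSON
#' @param path JSON path.
#' @param pooling A [pooling_map()].
#' @export
read_pooling_map <- function(path) {
  obj <- jsonlite::read_json(path)
  pooling_map(unlist(obj$mapping), unlist(obj$pooled_legend))
}

#' @rdname read_pooling_map
#' @export
write_pooling_map <- function(pooling, path) {
  jsonlite::write_json(
    list(
      mapping = as.list(pooling$mapping),
      pooled_legend = as.list(pooling$pooled_legend)
    ),
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Pool raw classes into broad categories
#'
#' Cellwise relabelling of raw cluster codes into pooled class codes; nodata
#' is preserved and total non-nodata cell count is conserved.
#'
#' @param raw A [habitat_grid()] of raw cluster codes.
#' @param pooling A [pooling_map()].
#' @return A [habitat_grid()] with the pooled legend.
#' @export
pool_classes <- function(raw, pooling) {
  present <- unique(raw$classes[!is.na(raw$classes)])
  raw_codes <- as.integer(names(pooling$mapping))
  missing <- setdiff(present, raw_codes)
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("raw codes with no pooled mapping: %s", paste(missing, collapse = ", ")),
      class = "scenhab_error_mapping"
    )
  }
  idx <- match(raw$classes, raw_codes)
  pooled <- matrix(unname(pooling$mapping)[idx], nrow(raw$classes), ncol(raw$classes))
  habitat_grid(pooled, raw$spec, pooling$pooled_legend)
}
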