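make_image <- function(bands, cell = 30) {
  spec <- grid_spec(nrow(bands[[1]]), ncol(bands[[1]]), cell)
  multiband_image(bands, spec)
}

test_that("PCA concentrates correlated bands on one component", {
  withr::with_seed(1, {
    b1 <- matrix(rnorm(100), 10, 10)
  })
  img <- make_image(list(b1 = b1, b2 = 3 * b1 + 5))
  red <- pca_reduce(img, 1)
  ev <- attr(red, "explained_variance")
  expect_equal(ev[1], 1, tolerance = 1e-12)
})

test_that("full-rank PCA scores reconstruct the standardised data", {
  withr::with_seed(2, {
    bands <- lapply(1:3, function(i) matrix(rnorm(225, sd = i), 15, 15))
  })
  names(bands) <- paste0("b", 1:3)
  img <- make_image(bands)
  red <- pca_reduce(img, 3)
  V <- attr(red, "loadings")
  cells <- seq_len(225)
  S <- sapply(red$bands, function(b) b[cells])
  X <- sapply(bands, function(b) b[cells])
  Z <- scale(X)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  expect_equal(unname(S %*% t(V)), unname(Z), tolerance = 1e-8)
})

test_that("PCA scores match a dense eigendecomposition oracle", {
  withr::with_seed(3, {
    bands <- lapply(1:3, function(i) matrix(rnorm(225), 15, 15))
  })
  names(bands) <- paste0("b", 1:3)
  img <- make_image(bands)
  red <- pca_reduce(img, 2)
  X <- sapply(bands, as.vector)
  Z <- scale(X)
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  for (j in 1:2) {
    oracle <- Z %*% eig$vectors[, j]
    got <- as.vector(red$bands[[j]])
    # sign convention may differ from the oracle's
    err <- min(max(abs(got - oracle)), max(abs(got + oracle)))
    expect_lt(err, 1e-8)
  }
  expect_error(
    pca_reduce(make_image(list(a = matrix(1, 5, 5), b = matrix(2, 5, 5))), 1),
    class = "scenhab_error_degenerate"
  )
})

test_that("k-means separates well-separated blobs and is seeded", {
  withr::with_seed(4, {
    blob <- rbind(
      matrix(rnorm(40, mean = 0, sd = 0.05), 20, 2),
      matrix(rnorm(40, mean = 5, sd = 0.05), 20, 2)
    )
  })
  bands <- list(b1 = matrix(blob[, 1], 8, 5), b2 = matrix(blob[, 2], 8, 5))
  img <- make_image(bands)
  cls <- kmeans_classify(img, k = 2, seed = 1)
  truth <- matrix(rep(1:2, each = 20), 8, 5)
  agree <- mean(cls$classes == truth)
  expect_true(agree == 1 || agree == 0) # equal up to label swap
  cls2 <- kmeans_classify(img, k = 2, seed = 1)
  expect_identical(cls$classes, cls2$classes)
})

test_that("k-means with restarts attains the exhaustive-partition optimum", {
  withr::with_seed(5, {
    X <- matrix(rnorm(24), 12, 2)
  })
  bands <- list(b1 = matrix(X[, 1], 4, 3), b2 = matrix(X[, 2], 4, 3))
  img <- make_image(bands)
  cls <- kmeans_classify(img, k = 2, seed = 7, n_init = 20)
  expect_equal(attr(cls, "withinss"), oracle_best_2partition_ss(X), tolerance = 1e-9)
})

test_that("k-means degenerate and error cases behave", {
  # k equal to the number of distinct pixels: zero within-cluster SS
  vals <- matrix(c(1, 2, 3, 4), 2, 2)
  img <- make_image(list(b1 = vals, b2 = vals))
  cls <- kmeans_classify(img, k = 4, seed = 1)
  expect_equal(attr(cls, "withinss"), 0)
  expect_error(kmeans_classify(img, k = 5, seed = 1), class = "scenhab_error_parameter")
})

test_that("k-means objective is non-increasing across Lloyd iterations", {
  withr::with_seed(6, {
    X <- matrix(rnorm(120), 60, 2)
    init <- X[sample.int(60, 4), ]
  })
  obj <- vapply(1:8, function(iters) {
    suppressWarnings(
      stats::kmeans(X, centers = init, iter.max = iters, algorithm = "Lloyd")$tot.withinss
    )
  }, numeric(1))
  expect_true(all(diff(obj) <= 1e-9))
})

test_that("pooling relabels, conserves counts, and rejects unmapped codes", {
  g <- make_test_grid(n = 15, k = 18, seed = 8)
  mapping <- stats::setNames(((1:18 - 1) %% 6) + 1, 1:18)
  pm <- pooling_map(mapping, stats::setNames(1:6, paste0("pool_", 1:6)))
  pooled <- pool_classes(g, pm)
  # per-code counts equal sums of mapped raw-id counts
  for (p in 1:6) {
    raws <- as.integer(names(mapping)[mapping == p])
    expect_equal(sum(pooled$classes == p), sum(g$classes %in% raws))
  }
  expect_equal(
    sum(!is.na(pooled$classes)), sum(!is.na(g$classes))
  )
  # identity mapping returns the same classes
  idmap <- pooling_map(
    stats::setNames(1:18, 1:18),
    stats::setNames(1:18, paste0("c", 1:18))
  )
  expect_equal(pool_classes(g, idmap)$classes, g$classes)
  # unmapped code errors
  pm_bad <- pooling_map(
    stats::setNames(1:6, 1:6),
    stats::setNames(1:6, paste0("c", 1:6))
  )
  expect_error(pool_classes(g, pm_bad), class = "scenhab_error_mapping")
})

test_that("pooling maps round-trip through JSON", {
  pm <- pooling_map(
    stats::setNames(c(1, 1, 2, 3), 1:4),
    c(low = 1, mid = 2, high = 3)
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_pooling_map(pm, path)
  pm2 <- read_pooling_map(path)
  expect_equal(pm2$mapping, pm$mapping)
  expect_equal(pm2$pooled_legend, pm$pooled_legend)
})
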