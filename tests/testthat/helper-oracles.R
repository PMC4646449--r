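# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# Per-cell focal proportion by direct window enumeration.
oracle_focal_proportion <- function(classes, code, radius, cell_size) {
  nr <- nrow(classes)
  nc <- ncol(classes)
  r_cells <- floor(radius / cell_size)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(classes[i, j])) next
      hits <- 0L
      avail <- 0L
      for (di in -r_cells:r_cells) {
        for (dj in -r_cells:r_cells) {
          if ((di * cell_size)^2 + (dj * cell_size)^2 > radius^2) next
          ii <- i + di
          jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          if (is.na(classes[ii, jj])) next
          avail <- avail + 1L
          if (classes[ii, jj] == code) hits <- hits + 1L
        }
      }
      out[i, j] <- hits / avail
    }
  }
  out
}

# Recursive flood fill patch labelling.
oracle_label_patches <- function(is_target, connectivity = 8L) {
  nr <- nrow(is_target)
  nc <- ncol(is_target)
  labels <- matrix(NA_integer_, nr, nc)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L) {
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  lab <- 0L
  for (start in which(is_target)) {
    if (!is.na(labels[start])) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      ci <- (cur - 1L) %% nr + 1L
      cj <- (cur - 1L) %/% nr + 1L
      for (k in seq_len(nrow(offs))) {
        ni <- ci + offs[k, 1]
        nj <- cj + offs[k, 2]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (!is_target[ni, nj]) next
        lin <- ni + (nj - 1L) * nr
        if (is.na(labels[lin])) {
          labels[lin] <- lab
          queue <- c(queue, lin)
        }
      }
    }
  }
  list(labels = labels, np = lab)
}

# Edge faces by direct per-cell face inspection.
oracle_total_edge_faces <- function(is_target, boundary_edge = TRUE) {
  nr <- nrow(is_target)
  nc <- ncol(is_target)
  faces <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!is_target[i, j]) next
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- i + o[1]
        nj <- j + o[2]
        outside <- ni < 1 || ni > nr || nj < 1 || nj > nc
        if (outside) {
          if (boundary_edge) faces <- faces + 1L
        } else if (!is_target[ni, nj]) {
          faces <- faces + 1L
        }
      }
    }
  }
  faces
}

# Exact two-sided Mann-Whitney p by enumerating all label assignments.
oracle_mw_exact_p <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  n_tot <- length(pooled)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combs <- utils::combn(n_tot, m)
  us <- apply(combs, 2, function(idx) {
    aa <- pooled[idx]
    bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  mn2 <- m * (n_tot - m) / 2
  mean(abs(us - mn2) >= abs(u_obs - mn2) - 1e-9)
}

# Kruskal-Wallis H from the rank formula (no tie correction; callers use
# tie-free data).
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups)
  r <- rank(pooled)
  n <- length(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, idx, sum)
  12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
}

# Minimum within-cluster SS over every 2-partition of the rows of X.
oracle_best_2partition_ss <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    if (sum(grp) == 0 || sum(grp) == n) next
    ss <- 0
    for (g in 0:1) {
      sub <- X[grp == g, , drop = FALSE]
      ctr <- colMeans(sub)
      ss <- ss + sum(sweep(sub, 2, ctr)^2)
    }
    best <- min(best, ss)
  }
  best
}

# A small multi-class grid fixture shared by several tests.
make_test_grid <- function(n = 20, k = 3, seed = 1, cell_size = 30) {
  withr::with_seed(seed, {
    classes <- matrix(sample.int(k, n * n, replace = TRUE), n, n)
  })
  habitat_grid(
    classes, grid_spec(n, n, cell_size),
    stats::setNames(seq_len(k), paste0("class_", seq_len(k)))
  )
}
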