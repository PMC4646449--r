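#' Synthetic landscape, imagery and presence generators
#'
#' These generators produce landscapes with known structure so that every
#' stage of the pipeline (classification, focal predictors, model fitting,
#' scenario simulation, comparison) can be exercised end-to-end without any
#' external data.
#'
#' @name synthetic
NULL

# Smooth, unit-variance Gaussian latent field with an isotropic correlation
# length, via FFT (periodic) filtering of white noise. Deterministic given
# the current RNG state.
latent_field <- function(n_rows, n_cols, corr_cells) {
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (corr_cells <= 0) {
    return(noise)
  }
  di <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dj <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  d2 <- outer(di^2, dj^2, "+")
  kern <- exp(-d2 / (2 * corr_cells^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (n_rows * n_cols)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a spatially autocorrelated categorical landscape
#'
#' A smooth Gaussian latent field (plus a weaker, rougher component that
#' breaks up pure banding) is thresholded at cumulative-prevalence ranks, so
#' realised class areas match the prevalence targets exactly up to rounding.
#' Deterministic given `seed`.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_size Cell size in metres.
#' @param prevalence Named numeric vector of target class proportions (names
#'   become the legend; codes are assigned 1..k in order). Must sum to 1.
#' @param correlation_length Spatial correlation length in metres
#'   (>= cell_size).
#' @param seed Integer RNG seed.
#' @return A [habitat_grid()].
#' @export
synth_habitat <- function(n_rows = 100L, n_cols = 100L, cell_size = 100,
                          prevalence = paper_like_prevalence(),
                          correlation_length = 800, seed = 1L) {
  if (any(prevalence < 0) || sum(prevalence) <= 0) {
    rlang::abort("prevalences must be nonnegative and not all zero",
      class = "scenhab_error_parameter"
    )
  }
  if (correlation_length < cell_size) {
    rlang::abort("correlation_length must be >= cell_size", class = "scenhab_error_parameter")
  }
  prevalence <- prevalence / sum(prevalence)
  k <- length(prevalence)
  spec <- grid_spec(n_rows, n_cols, cell_size)
  corr_cells <- correlation_length / cell_size
  latent <- withr::with_seed(seed, {
    latent_field(n_rows, n_cols, corr_cells) +
      0.4 * latent_field(n_rows, n_cols, corr_cells / 3)
  })
  n <- n_rows * n_cols
  cuts <- round(cumsum(prevalence) * n)
  ranks <- rank(latent, ties.method = "first")
  codes <- matrix(findInterval(ranks, c(0, cuts), left.open = TRUE), n_rows, n_cols)
  codes[codes > k] <- k
  legend <- stats::setNames(seq_len(k), names(prevalence))
  habitat_grid(codes, spec, legend)
}

#' Synthetic multiband image over a habitat map
#'
#' Gives each habitat class a distinct spectral signature (a binary code
#' scaled by `signature_spacing` across bands) and adds per-pixel Gaussian
#' noise, producing an image from which the unsupervised classification
#' should recover the habitat map when the noise is small relative to the
#' spacing.
#'
#' @param habitat A [habitat_grid()].
#' @param n_bands Number of bands (>= 2).
#' @param noise_sd Gaussian noise standard deviation per band.
#' @param signature_spacing Distance between signature levels.
#' @param seed Integer RNG seed.
#' @return A [multiband_image()].
#' @export
synth_multiband <- function(habitat, n_bands = 6L, noise_sd = 0.1,
                            signature_spacing = 1, seed = 1L) {
  if (n_bands < 2) rlang::abort("n_bands must be >= 2", class = "scenhab_error_parameter")
  codes <- sort(unname(habitat$legend))
  mu <- sapply(seq_len(n_bands), function(b) {
    signature_spacing * ((codes %/% 2^(b - 1)) %% 2)
  })
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  spec <- habitat$spec
  idx <- match(habitat$classes, codes)
  bands <- withr::with_seed(seed, {
    lapply(seq_len(n_bands), function(b) {
      m <- matrix(mu[idx, b], spec$n_rows, spec$n_cols)
      if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m))
      m[is.na(habitat$classes)] <- NA
      m
    })
  })
  names(bands) <- paste0("band_", seq_len(n_bands))
  multiband_image(bands, spec)
}

#' Sample presences from a known suitability function
#'
#' Cells are drawn without replacement with probability proportional to
#' `exp(lambda_true . f(x))`, where `f(x)` are the stack layer values. This
#' emulates display-site locations arising from a known Gibbs suitability
#' surface, the ground truth for model-recovery experiments.
#'
#' @param stack A [focal_stack()].
#' @param true_lambdas Named numeric vector of weights over stack layers
#'   (missing layers get weight 0).
#' @param n Number of presences (at most the number of defined cells).
#' @param seed Integer RNG seed.
#' @return A tibble with `cell` (linear index), `row`, `col`, `x`, `y`.
#' @export
synth_presences <- function(stack, true_lambdas, n, seed = 1L) {
  cells <- stack_defined_cells(stack)
  if (n > length(cells)) {
    rlang::abort("n exceeds the number of defined cells", class = "scenhab_error_parameter")
  }
  eta <- true_suitability_eta(stack, true_lambdas, cells)
  w <- exp(eta - max(eta))
  picked <- withr::with_seed(seed, sample(cells, n, prob = w))
  nr <- stack$spec$n_rows
  row <- ((picked - 1L) %% nr) + 1L
  col <- ((picked - 1L) %/% nr) + 1L
  xy <- cell_centers(stack$spec, row, col)
  tibble::tibble(cell = picked, row = row, col = col, x = xy$x, y = xy$y)
}

true_suitability_eta <- function(stack, true_lambdas, cells) {
  lam <- stats::setNames(numeric(length(stack$layers)), names(stack$layers))
  common <- intersect(names(true_lambdas), names(lam))
  lam[common] <- true_lambdas[common]
  P <- stack_matrix(stack, cells)
  drop(P %*% lam)
}

#' True suitability surface of a synthetic Gibbs model
#'
#' @inheritParams synth_presences
#' @return A [continuous_grid()] of `exp(lambda . f(x))`, normalised to sum
#'   to 1 over defined cells.
#' @export
true_suitability <- function(stack, true_lambdas) {
  cells <- stack_defined_cells(stack)
  eta <- true_suitability_eta(stack, true_lambdas, cells)
  m <- max(eta)
  raw <- exp(eta - m) / sum(exp(eta - m))
  vals <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  vals[cells] <- raw
  continuous_grid(vals, stack$spec, name = "true_suitability")
}

#' Upland-mosaic preset
#'
#' Default class prevalences for a six-class upland working landscape
#' (human-dominated, grazed land, moorland/grouse moor, open-canopy forestry,
#' closed-canopy forestry, water bodies), the matching land-use-change
#' scenarios, and an altitude covariate.
#'
#' @return `paper_like_prevalence()`: named numeric vector summing to 1.
#' @export
paper_like_prevalence <- function() {
  c(
    human = 0.03, grazed = 0.35, moorland = 0.30,
    open_canopy = 0.12, closed_canopy = 0.15, water = 0.05
  )
}

#' @rdname paper_like_prevalence
#' @param n_seeds,growth_prob,connectivity Growth parameters shared by all
#'   five scenarios.
#' @return `paper_like_scenarios()`: named list of five [scenario()]s
#'   (increased open-canopy forestry, reduced grazing, increased grouse moor,
#'   increased grazing, increased closed-canopy forestry).
#' @export
paper_like_scenarios <- function(n_seeds = 20L, growth_prob = 0.25, connectivity = 8L) {
  mk <- function(name, rules) {
    scenario(name, rules,
      n_seeds = n_seeds, growth_prob = growth_prob,
      connectivity = connectivity
    )
  }
  list(
    increased_open_canopy = mk("increased_open_canopy", dplyr::bind_rows(
      conversion_rule("grazed", "open_canopy", 0.07),
      conversion_rule("moorland", "open_canopy", 0.03)
    )),
    reduced_grazing = mk("reduced_grazing", dplyr::bind_rows(
      conversion_rule("grazed", "moorland", 0.07),
      conversion_rule("grazed", "open_canopy", 0.03)
    )),
    increased_grouse_moor = mk("increased_grouse_moor", dplyr::bind_rows(
      conversion_rule("grazed", "moorland", 0.05),
      conversion_rule("open_canopy", "moorland", 0.05)
    )),
    increased_grazing = mk("increased_grazing", dplyr::bind_rows(
      conversion_rule("moorland", "grazed", 0.10)
    )),
    increased_closed_canopy = mk("increased_closed_canopy", dplyr::bind_rows(
      conversion_rule("moorland", "closed_canopy", 0.05),
      conversion_rule("grazed", "closed_canopy", 0.05)
    ))
  )
}

#' @rdname paper_like_prevalence
#' @param n_rows,n_cols,cell_size,correlation_length,seed Passed to
#'   [synth_habitat()].
#' @return `paper_like_landscape()`: list with `grid` (six-class
#'   [habitat_grid()]), `altitude` (a [continuous_grid()] ramp with smooth
#'   relief, in metres) and `true_lambdas` (a plausible ground-truth weight
#'   vector for recovery experiments: positive for moorland and open-canopy
#'   proportion, negative for closed-canopy and grazed).
#' @export
paper_like_landscape <- function(n_rows = 100L, n_cols = 100L, cell_size = 100,
                                 correlation_length = 800, seed = 1L) {
  grid <- synth_habitat(
    n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
    prevalence = paper_like_prevalence(),
    correlation_length = correlation_length, seed = seed
  )
  relief <- withr::with_seed(seed + 1L, latent_field(n_rows, n_cols, correlation_length / cell_size))
  ramp <- matrix(rep(seq(0, 1, length.out = n_rows), n_cols), n_rows, n_cols)
  alt <- 46 + (1078 - 46) * (0.7 * ramp + 0.3 * (relief - min(relief)) / diff(range(relief)))
  list(
    grid = grid,
    altitude = continuous_grid(alt, grid$spec, name = "altitude"),
    true_lambdas = c(
      moorland = 2.5, open_canopy = 2.0, grazed = -1.5,
      closed_canopy = -2.0, altitude = -0.002 # per metre: ~ -2 across the relief
    )
  )
}
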